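---
title: "Methods: the ubinder design funnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ubinder design funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ubinder` implements a staged funnel for designing small binding proteins on
the human ubiquitin scaffold: curate a library of scaffold variants, fit a
generative sequence model, sample and filter de novo candidates, triage
docking poses, post-process end-state binding energies, and prioritise point
mutants for affinity maturation. This vignette records the models, the
parameters that matter, the numerical conventions, and the choices made
where the design was genuinely open. External heavy tools (structure
prediction, docking, Monte-Carlo refinement, molecular dynamics) are out of
scope by construction: their outputs — predicted models with confidence
tracks, scored pose decks, per-frame energies, per-residue decompositions —
are the package's *inputs*, and seeded synthetic generators emulate them for
testing.

## Library curation

A scaffold record is a sequence over the 20-letter amino-acid alphabet with
optional affinity annotations: the dissociation constant K_D in nM, a target
label, and a binder class. Classes follow the conventional banding — strong
binders (SB) below 10 nM, medium binders (MB) from 10 nM up to but excluding
100 nM, weak binders (WB) at 100 nM and above — half-open on the strong side
so every positive K_D maps to exactly one class. NB ("no binding detected")
is an annotation-only class, never produced from a numeric K_D.

Head-to-tail dimeric constructs concatenate two scaffold units, each led by
one of the N-terminal motifs MQI, MRI, MAS or MTI. `split_dimer()` cuts at
the *leftmost* motif occurrence strictly after the first position and
ignores later occurrences, so a dimer yields exactly two monomers and
residues are conserved exactly. Deduplication (`deduplicate()`, default
threshold 0.99) is greedy and single-pass: the first occurrence wins and
order is preserved. This is deliberately order-dependent — it is the
simplest rule that is bit-reproducible.

Pairwise identity is defined once, package-wide: global Needleman–Wunsch
alignment under BLOSUM62 with affine gap penalties (open −10, extend −0.5),
identity = identical aligned columns / total alignment length, *including*
gap columns (also terminal ones). This denominator makes the measure
symmetric and equal to 1 exactly when the sequences are equal. A `max_gap`
cap (default 50) bounds the longest contiguous gap; alignments that exceed
it raise an error rather than silently returning a meaningless number.
Inside `deduplicate()` two sound shortcuts avoid the quadratic alignment
cost: identity can never exceed min(len)/max(len), and for equal-length
pairs at high thresholds a gapped alignment is bounded below the threshold
(each gap pair adds three non-identical columns), so ungapped identity
decides. The test suite asserts equivalence of the pruned and the all-pairs
routes on mixed libraries.

## The sequence generator

The generator is an LSTM variational autoencoder over fixed-length one-hot
encodings: `max_len` positions (default 164), each a 21-way indicator over
the 20 amino acids plus one padding token that fills positions after the
sequence end. The encoder is an LSTM (256 units by default) whose final
hidden state passes through a 128-unit tanh layer; two parallel linear heads
emit the mean and log-variance of a diagonal-Gaussian posterior over a
latent vector (default dimension 128 — the fully connected width is read as
the size of the representation from which the latent statistics are
produced, and the dimension is configurable). Two linear tanh maps from the
latent vector initialise the decoder LSTM's hidden and cell states
(interpreting "two layers to decode hidden and current states"); the decoder
LSTM (256 units) then emits 21-way token logits position by position.

Training minimises the per-sequence ELBO loss: token-level cross-entropy
reconstruction over **all** `max_len` positions (the padding tail is part of
the target, which is how the model learns to terminate) plus the analytic
KL divergence from the standard-normal prior, unweighted (no annealing).
The decoder is teacher-forced during training — the standard choice, made
explicitly here. Optimisation is Adam (learning rate 0.001 by default) on
seeded minibatches; a seeded random split holds out 10 % of records for
validation, validation loss is computed at the posterior mean (no sampling
noise, so early stopping is stable), and training stops at `max_epochs` or
after `early_stop_patience` (default 5) epochs without validation
improvement, retaining the parameters of the best validation epoch. The
epoch count at which a given library converges is an outcome, not a
parameter.

The entire model — forward pass, backpropagation through time, Adam — is
written in base R with batched matrix operations. The gradients were
verified against central finite differences during development; the
determinism contract (identical seed ⇒ bit-identical history, parameters
and generated sequences, also across a save/load round trip) is part of the
test suite.

Generation decodes latent draws z ~ N(0, I) autoregressively: at each
position the logits are divided by a temperature and sampled through the
softmax; temperatures at or below 10⁻⁶ degrade to argmax (greedy) decoding.
Decoding stops at the first padding token, so generated sequences never
contain the padding symbol. Higher temperatures increase diversity — the
suite checks the statistical form of this claim (mean pairwise identity at
temperature 1.5 ≤ that at 0.5, averaged over 20 seeds) rather than a
per-seed inequality, which would not be guaranteed.

## Candidate filtration

`filter_generated()` keeps a candidate iff its length lies in 72–84
residues and its identity to wild-type ubiquitin (the packaged 76-residue
reference) lies in 0.75–0.90. Both windows are inclusive at both ends; the
bounds are configurable (an alternative length reading of 72–82 exists in
the source material's figure caption — the window is a parameter precisely
so either convention can be applied). Sequences so divergent that their
alignment would exceed `max_gap` report NA identity and are rejected, which
makes the filter total over arbitrary generator output. `plddt_filter()`
discards a predicted model if *any* residue has confidence below the floor
(default pLDDT 50) — the strictest consistent reading of rejecting models
with low-confidence regions; windowed alternatives are deliberately not
implemented.

## Structure geometry

Structures are reduced models: ordered Cα (optionally backbone N, CA, C, O)
atoms with chain, 1-based author residue numbers and coordinates in
Ångström; first-listed alternate locations win, HETATM records are ignored.
Superposition is the Kabsch SVD solution with the determinant correction
that excludes reflections. Two RMSD notions are built on it:

* `aligned_ca_rmsd()` for homologous proteins: sequence-align the Cα
  traces, take all mutually aligned (non-gap in both) columns — including
  substituted positions, since the correspondence, not residue identity, is
  what matters — and return the optimally superposed RMSD. Fewer than three
  matched pairs is a degenerate-alignment error.
* `ligand_rmsd()` between poses of one deck: superpose the two receptor
  copies, apply that transform to the second ligand, and return the plain
  (no re-superposition) RMSD between ligand copies. This is symmetric and
  invariant to rigid motions applied jointly to either pose's
  receptor+ligand pair. An atom-selection flag (`"calpha"` default,
  `"backbone"`) covers both the docking and the trajectory use of the same
  definition — one code path, two selections.

## Pose triage

The docking funnel has three rules, each with an explicit boundary
convention:

* **Interface proximity**: keep a pose iff some receptor-patch Cα is within
  10 Å of some ligand-patch Cα; exactly 10 Å counts as in contact. An
  optional exclusion patch (e.g. a dimerisation surface) additionally
  discards poses whose ligand comes within the cutoff of it.
* **Greedy energy/diversity clustering**: visit poses by ascending score
  (ties broken by pose id), keep a pose iff its ligand-RMSD to *every*
  already-kept pose exceeds 2 Å (exactly 2 Å is rejected), stop at 50 kept.
  Comparing against all kept poses (leader clustering) rather than only the
  last kept one prevents near-duplicates of early poses from re-entering.
  An independent brute-force implementation of the same rule
  (`greedy_reference()`, full pairwise RMSD matrix plus a plain loop) is the
  oracle in equivalence tests and provides fixture ground truth.
* **Cross-candidate selection**: summarise each candidate by the mean of
  its k best pose energies (k = 50 at the docking stage, k = 10 at the
  refinement stage — one operation, two parameterisations) and discard
  candidates strictly above the across-candidate mean. Candidates exactly
  at the mean survive, so at least one candidate always does.

## Energetics

End-state binding energies follow the standard snapshot form: per frame
ΔG_t = E_complex − E_receptor − E_ligand (each component already includes
its solvation term), summarised by the mean and its standard error.
Conformational entropy is excluded by construction. Relative affinity is
ΔΔG = ΔG_variant − ΔG_parent, negative meaning predicted improvement.
Per-residue decompositions sum each interface residue's pairwise
interactions over all residues; hotspots are residues strictly below
−2 kcal/mol, and mutable positions are the interface complement (at or
above −2, inclusive precisely so hotspots and mutable positions partition
any interface set).

Candidate banding into NB/WB, MB, SB is quantile-based: no energy
thresholds exist for these computational bands, so the package ranks by ΔG
and splits by configurable fractions (default terciles, ties broken by
candidate id for order invariance). The historically observed 6/9/11 split
of 26 simulation-stage candidates is reproducible by configuring those
fractions — it is an observed outcome, not a derivable rule, and the
package treats it as such.

## Affinity maturation

Candidate pools (e.g. 100 inverse-folding variants per parental hit) are
clustered greedily at 97.5 % identity: each sequence joins the first
centroid it matches at or above the threshold (inclusive, making the
boundary testable) or founds a new cluster; the first member is the
representative, since the external tool this stands in for does not specify
its choice. Multi-mutants are decomposed against the fixed-length parent —
indel-bearing variants are rejected rather than aligned — and the union of
their substitutions, deduplicated and ordered by position then residue,
gives the single-mutant panel. Consensus doubles/triples combine only
improving singles (ΔΔG < 0, ranked most-improving first) at pairwise
distinct positions, up to order 3. Ranking uses whole-single ΔΔG; how "the
mutations that contribute more" should be attributed is not specified more
finely, and per-mutation energy attribution is deliberately out of scope.
Curated extra singles from prior experimental knowledge enter as a
user-supplied scored-singles file (`read_scored_singles()`), not by
inference.

## Synthetic fixtures: what they emulate, and what they do not

The generators in `fixtures.R` emulate the *shape* of the study inputs,
with planted answers:

* `make_library()` — 759 records (329 monomeric) of ubiquitin-derived
  variants (5–20 substitutions, occasional C-terminal-loop insertions up to
  length 84), per-target class marginals HER2 72/59/16, FINC ED-B 36/32/18,
  Others 127/208/191, K_D drawn log-uniform inside each class band
  (SB [0.1, 10), MB [10, 100), WB [100, 10000) nM — the bands' edges are
  the only given quantities, and log-uniform is the neutral choice within
  them). Dimer units are frequently reused between constructs so that
  splitting plus deduplication collapses the library, as real repeated
  scaffold units do. Variants are resampled if a substitution creates an
  internal split motif, keeping planted dimer junctions unambiguous.
* `make_pose_deck()` — a toy helical receptor/ligand complex with rigid
  random perturbations; scores −30/(1 + RMSD-to-reference) (+ optional
  noise), so the reference pose is the planted best and the greedy oracle's
  output is exact ground truth.
* `make_decomposition()` — explicit pairwise interaction matrices with
  planted strong rows (sums below −2.5) over weak background rows (sums in
  (−0.9, 0)), so hotspot recovery is exact and the decomposition conserves
  the matrix total.
* `make_plddt_tracks()` — confident-core/low-terminal tracks with a planted
  number of sub-floor residues (11 of 112 by default).

None of these imitate binding physics, docking score landscapes or real
generative-model sequence statistics. Passing tests therefore demonstrate
algorithmic correctness (boundaries, invariants, determinism, oracle
equivalence), not predictive validity on real systems.

## Problem sizes and numerical choices

The production-scale architecture defaults (256/128/128/256 units) are the
package's reference configuration; the test suite and acceptance script
exercise the identical code at compact widths (24–48 LSTM units, latent
6–8, 2–5 epochs for convergence checks, 150 epochs for the memorization
check) and `max_len` 80–88, which train in seconds to about a minute on one
CPU — the model code has no width-dependent branches, so the small
configurations test the same arithmetic. Other fixed numerical conventions:
Kabsch uses SVD with reflection correction; softmax is computed with the
max subtracted; reconstruction cross-entropy adds 10⁻¹² inside the
logarithm; score ties in pose triage and ΔG ties in banding are broken by
id; all random draws flow from explicit integer seeds through a helper that
restores the caller's RNG state.

## Known limitations

* The VAE is CPU-bound R; at the full 256-unit production width, training
  on hundreds of sequences takes hours rather than minutes. The
  architecture is faithful; the default width is not the testing width.
* `deduplicate()` and `cluster_pool()` are O(n²) in the worst case;
  pruning makes curation of ~10³ monomers fast, but pools of 10⁵ would
  need an indexed clusterer.
* Identity is defined via the optimal-*score* alignment; among tied-score
  alignments the reported identity follows the aligner's traceback.
* The funnel's intermediate stage counts depend on inputs the package does
  not model (real docking scores, real predicted structures); fixture runs
  validate the plumbing and the selection rules, not the counts a real
  campaign would produce.
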