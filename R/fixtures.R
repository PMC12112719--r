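#' Synthetic-fixture configuration
#'
#' Settings for the seeded synthetic-data generators that emulate the
#' study inputs: a scaffold library with per-target binder-class
#' marginals, docking pose decks with a planted low-energy diverse subset,
#' per-residue decomposition tables with planted hotspots, and
#' model-confidence tracks with planted failures.
#'
#' @param seed Integer master seed; all generators are bit-reproducible
#'   per seed.
#' @param library_size Total sequence records (default 759).
#' @param monomer_count How many records are monomeric (default 329); the
#'   remainder are head-to-tail dimeric constructs.
#' @param class_marginals Integer matrix (targets x classes SB/MB/WB) of
#'   planted per-target class counts; must sum to \code{library_size}.
#'   The default reproduces the training-library composition used
#'   throughout the package: HER2 72/59/16, FINC ED-B 36/32/18, Others
#'   127/208/191.
#' @param pose_deck_size Poses per synthetic deck (default 60).
#' @param planted_hotspot_count Strong residues planted per decomposition
#'   table (default 3).
#' @param plddt_fail_count Confidence tracks planted to fail the pLDDT
#'   floor (default 11 of 112).
#' @return A list of class \code{"fixture_config"}.
#' @export
fixture_config <- function(seed = 1L, library_size = 759L,
                           monomer_count = 329L,
                           class_marginals = default_class_marginals(),
                           pose_deck_size = 60L,
                           planted_hotspot_count = 3L,
                           plddt_fail_count = 11L) {
  if (sum(class_marginals) != library_size)
    abort_input("class marginals must sum to library_size")
  if (monomer_count > library_size)
    abort_input("monomer_count cannot exceed library_size")
  structure(list(seed = as.integer(seed),
                 library_size = as.integer(library_size),
                 monomer_count = as.integer(monomer_count),
                 class_marginals = class_marginals,
                 pose_deck_size = as.integer(pose_deck_size),
                 planted_hotspot_count = as.integer(planted_hotspot_count),
                 plddt_fail_count = as.integer(plddt_fail_count)),
            class = "fixture_config")
}

#' Default per-target binder-class counts of the training library
#'
#' @return A 3 x 3 integer matrix (rows HER2, FINC_EDB, Others; columns
#'   SB, MB, WB) summing to 759.
#' @export
default_class_marginals <- function() {
  m <- matrix(c(72L, 59L, 16L,
                36L, 32L, 18L,
                127L, 208L, 191L), nrow = 3, byrow = TRUE,
              dimnames = list(c("HER2", "FINC_EDB", "Others"),
                              c("SB", "MB", "WB")))
  m
}

#' Scale the default class marginals to a different library size
#'
#' Proportionally rescales the per-target class counts to sum to \code{n}
#' (rounding residue added to the largest cell), for reduced-scale
#' fixture libraries.
#'
#' @param n Target library size.
#' @return A 3 x 3 integer matrix summing to \code{n}.
#' @export
scaled_class_marginals <- function(n) {
  base <- default_class_marginals()
  m <- round(base * n / sum(base))
  i <- which.max(m)
  m[i] <- m[i] + n - sum(m)
  storage.mode(m) <- "integer"
  m
}

# K_D bands (nM, log-uniform) per class.
kd_bands <- list(SB = c(0.1, 10), MB = c(10, 100), WB = c(100, 10000))

draw_kd <- function(class) {
  b <- kd_bands[[class]]
  exp(stats::runif(1, log(b[1]), log(b[2]) - 1e-9))
}

# One ubiquitin-derived monomer variant: 5-20 substitutions, occasional
# short insertion in the C-terminal loop (length capped at 84). Resampled
# until it contains no internal split motif, so planted dimer junctions
# stay unambiguous.
random_monomer <- function(motifs) {
  wt <- ubiquitin_wt()
  repeat {
    chars <- strsplit(wt, "")[[1]]
    nsub <- sample(5:20, 1)
    pos <- sample(4:length(chars), nsub) # keep the N-terminal motif intact
    chars[pos] <- sample(AA_ALPHABET, nsub, replace = TRUE)
    if (stats::runif(1) < 0.3) {
      ins_len <- sample(1:8, 1)
      at <- sample(55:70, 1)
      chars <- append(chars, sample(AA_ALPHABET, ins_len, replace = TRUE),
                      after = at)
    }
    s <- paste(chars, collapse = "")
    if (nchar(s) <= 84 && is.na(internal_motif_pos(s, motifs))) return(s)
  }
}

#' Generate a synthetic scaffold library
#'
#' Builds a seeded library of ubiquitin-derived variants with planted
#' per-target binder-class counts: K_D values are drawn log-uniform
#' inside each class band (SB [0.1, 10), MB [10, 100), WB [100, 10000)
#' nM) so planted labels always agree with
#' \code{\link{classify_binder}}. A fraction of the records are dimeric
#' constructs formed by concatenating two motif-led monomers.
#'
#' @param cfg A \code{\link{fixture_config}}.
#' @param dataset_cfg A \code{\link{dataset_config}} supplying the split
#'   motifs.
#' @return A \code{\link{seq_records}} table of \code{library_size} rows.
#' @export
make_library <- function(cfg = fixture_config(),
                         dataset_cfg = dataset_config()) {
  with_seed(cfg$seed, {
    marg <- cfg$class_marginals
    targets <- rep(rownames(marg), times = rowSums(marg))
    classes <- unlist(lapply(rownames(marg), function(tg)
      rep(colnames(marg), times = marg[tg, ])))
    n <- cfg$library_size
    is_dimer <- rep(FALSE, n)
    if (cfg$monomer_count < n)
      is_dimer[sample.int(n, n - cfg$monomer_count)] <- TRUE
    motifs <- dataset_cfg$split_motifs
    # dimeric constructs frequently reuse an already-seen scaffold unit,
    # so monomer splitting followed by deduplication collapses the library
    units <- character(0)
    new_unit <- function(lead_motif = FALSE) {
      u <- random_monomer(motifs)
      if (lead_motif) substr(u, 1, 3) <- sample(motifs, 1)
      units <<- c(units, u)
      u
    }
    reuse_or_new <- function() {
      if (length(units) && stats::runif(1) < 0.5)
        units[[sample.int(length(units), 1)]]
      else new_unit(lead_motif = TRUE)
    }
    seqs <- vapply(seq_len(n), function(i) {
      if (!is_dimer[i]) return(new_unit())
      paste0(reuse_or_new(), reuse_or_new())
    }, "")
    kd <- vapply(classes, draw_kd, 0)
    seq_records(sprintf("fx_%03d", seq_len(n)), seqs, kd, targets, classes)
  })
}

# Idealised alpha-helix Calpha trace of n residues.
helix_ca <- function(n, origin = c(0, 0, 0)) {
  t <- seq_len(n)
  cbind(2.3 * cos(t * 100 * pi / 180),
        2.3 * sin(t * 100 * pi / 180),
        1.5 * t) + matrix(origin, n, 3, byrow = TRUE)
}

random_rotation <- function(max_angle_deg) {
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  ang <- stats::runif(1, 0, max_angle_deg) * pi / 180
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

mini_protein <- function(n, chain, origin = c(0, 0, 0)) {
  ca_structure(chain = chain, resno = seq_len(n), resname = "ALA",
               xyz = helix_ca(n, origin))
}

move_structure <- function(s, rot, trans) {
  xyz <- as.matrix(s[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  moved <- sweep(sweep(xyz, 2, ctr) %*% rot, 2, ctr + trans, `+`)
  s$x <- moved[, 1]; s$y <- moved[, 2]; s$z <- moved[, 3]
  s
}

#' Generate a synthetic docking pose deck with planted ground truth
#'
#' Builds a toy two-mini-protein complex (20-residue helical receptor,
#' 12-residue helical ligand) and a deck of rigid random perturbations of
#' the reference binding mode. Scores follow
#' \eqn{-k / (1 + RMSD_{ref})} plus optional Gaussian noise, so the
#' reference pose scores best by construction. The ground-truth kept set
#' for greedy energy/diversity clustering is computed with the
#' brute-force reference selector \code{\link{greedy_reference}}.
#'
#' @param cfg A \code{\link{fixture_config}}.
#' @param triage_cfg A \code{\link{triage_config}} used for the ground
#'   truth.
#' @param noise_sd Standard deviation of score noise (default 0: the
#'   planted ranking is exact).
#' @return A list with \code{deck} (a \code{\link{pose_deck}}) and
#'   \code{truth_ids} (pose ids of the ground-truth kept set, score
#'   order).
#' @export
make_pose_deck <- function(cfg = fixture_config(),
                           triage_cfg = triage_config(),
                           noise_sd = 0) {
  with_seed(derive_seed(cfg$seed, 101L), {
    receptor <- mini_protein(20L, "A")
    lig0 <- mini_protein(12L, "B", origin = c(12, 0, 10))
    ref <- pose("ref", receptor, lig0, score = 0)
    poses <- vector("list", cfg$pose_deck_size)
    for (i in seq_len(cfg$pose_deck_size)) {
      lig <- move_structure(lig0, random_rotation(40),
                            stats::rnorm(3, 0, 4))
      p <- pose(sprintf("p%03d", i), receptor, lig, score = 0)
      r <- ligand_rmsd(ref, p)
      p$score <- -30 / (1 + r) +
        if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
      poses[[i]] <- p
    }
    # the reference itself joins the deck as the planted best pose
    ref$score <- -30
    deck <- pose_deck(c(list(ref), poses))
    list(deck = deck, truth_ids = greedy_reference(deck, triage_cfg))
  })
}

#' Brute-force reference implementation of greedy pose selection
#'
#' Independent implementation of the energy/diversity clustering rule
#' used as ground truth for fixtures and as an oracle in equivalence
#' tests: precomputes the full pairwise ligand-RMSD matrix, then walks
#' the score-sorted deck keeping a pose iff it is farther than the
#' diversity radius from every pose kept so far.
#'
#' @param deck A \code{\link{pose_deck}}.
#' @param cfg A \code{\link{triage_config}}.
#' @return Character vector of kept pose ids in score order.
#' @export
greedy_reference <- function(deck, cfg = triage_config()) {
  n <- length(deck$poses)
  ids <- vapply(deck$poses, `[[`, "", "id")
  scores <- vapply(deck$poses, `[[`, 0, "score")
  rmat <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    rmat[i, j] <- rmat[j, i] <- ligand_rmsd(deck$poses[[i]], deck$poses[[j]])
  }
  kept <- integer(0)
  for (i in order(scores, ids)) {
    if (all(rmat[i, kept] > cfg$diversity_rmsd)) kept <- c(kept, i)
    if (length(kept) >= cfg$max_kept_poses) break
  }
  ids[kept]
}

#' Generate a synthetic per-residue decomposition with planted hotspots
#'
#' Builds an explicit pairwise interaction-energy matrix between a set of
#' ligand interface residues and the receptor residues, plants
#' \code{planted_hotspot_count} strong rows (summing below -2 kcal/mol)
#' among weak background rows (summing above -1), and returns the
#' row-sum decomposition table together with the matrix and the planted
#' truth.
#'
#' @param cfg A \code{\link{fixture_config}}.
#' @param n_residues Ligand interface residues in the table (default 15).
#' @param n_partner Receptor residues in the pairwise matrix (default
#'   20).
#' @return A list with \code{table} (a
#'   \code{\link{decomposition_table}} for chain B), \code{pairwise} (the
#'   interaction matrix) and \code{hotspot_resno} (planted strong
#'   residues).
#' @export
make_decomposition <- function(cfg = fixture_config(), n_residues = 15L,
                               n_partner = 20L) {
  with_seed(derive_seed(cfg$seed, 202L), {
    nh <- cfg$planted_hotspot_count
    if (nh > n_residues) abort_input("more hotspots than residues")
    hot <- sort(sample.int(n_residues, nh))
    pw <- matrix(0, n_residues, n_partner)
    for (r in seq_len(n_residues)) {
      # background rows sum in (-1, 0); hotspot rows sum below -2.5
      total <- if (r %in% hot) stats::runif(1, -8, -2.5)
               else stats::runif(1, -0.9, 0)
      w <- stats::runif(n_partner); w <- w / sum(w)
      pw[r, ] <- total * w
    }
    tab <- decomposition_table(chain = "B", resno = seq_len(n_residues),
                               dGres = rowSums(pw), resname = "ALA")
    list(table = tab, pairwise = pw, hotspot_resno = hot)
  })
}

#' Generate synthetic per-residue confidence tracks
#'
#' Produces \code{n} pLDDT tracks of plausible predicted-model shape
#' (confident core, less confident termini) and plants
#' \code{plddt_fail_count} tracks containing at least one residue below
#' the floor.
#'
#' @param cfg A \code{\link{fixture_config}}.
#' @param n Number of tracks (default 112).
#' @param length_range Residue-count range per track.
#' @param floor The confidence floor the failures are planted below
#'   (default 50).
#' @return A list with \code{models} (list usable with
#'   \code{\link{plddt_filter}}) and \code{fail_ids}.
#' @export
make_plddt_tracks <- function(cfg = fixture_config(), n = 112L,
                              length_range = c(72L, 84L), floor = 50) {
  if (cfg$plddt_fail_count > n) abort_input("more failures than tracks")
  with_seed(derive_seed(cfg$seed, 303L), {
    fail <- sort(sample.int(n, cfg$plddt_fail_count))
    models <- lapply(seq_len(n), function(i) {
      L <- sample(length_range[1]:length_range[2], 1)
      base <- 92 - 12 * exp(-0.5 * (seq_len(L) - 2)) -
        12 * exp(-0.5 * (L - seq_len(L)))
      track <- pmin(100, pmax(55, base + stats::rnorm(L, 0, 2)))
      if (i %in% fail) {
        at <- sample.int(L, 1)
        track[at] <- stats::runif(1, 20, floor - 0.5)
      }
      list(id = sprintf("model_%03d", i), plddt = track)
    })
    list(models = models, fail_ids = sprintf("model_%03d", fail))
  })
}

#' Generate synthetic per-frame energy components
#'
#' Per-frame complex/receptor/ligand energies whose differences are
#' normal with a planted mean and spread, for testing snapshot-averaged
#' binding-energy recovery.
#'
#' @param seed Integer seed.
#' @param n_frames Number of snapshots (default 500).
#' @param mean_dg Planted mean binding energy (kcal/mol, default -25).
#' @param sd_dg Planted frame-to-frame spread (default 3).
#' @return A data frame usable with \code{\link{binding_dg}}.
#' @export
make_energy_frames <- function(seed = 1L, n_frames = 500L, mean_dg = -25,
                               sd_dg = 3) {
  with_seed(seed, {
    er <- stats::rnorm(n_frames, -5500, 20)
    el <- stats::rnorm(n_frames, -900, 10)
    dg <- stats::rnorm(n_frames, mean_dg, sd_dg)
    data.frame(frame = seq_len(n_frames), E_complex = er + el + dg,
               E_receptor = er, E_ligand = el)
  })
}
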