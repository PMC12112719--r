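Package: ubinder
Title: Design and Triage of Ubiquitin-Scaffold Protein Binders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A combined machine-learning and molecular-modelling funnel for
    engineering small ubiquitin-scaffold binding proteins. Curates scaffold
    sequence libraries (dimer splitting, deduplication, affinity-class
    labelling), fits an LSTM variational autoencoder to generate de novo
    scaffold sequences, filters candidates by identity to wild-type
    ubiquitin, length and per-residue model confidence (pLDDT), triages
    docking pose decks by interface proximity and energy/diversity greedy
    clustering, post-processes end-state binding energies (snapshot-averaged
    binding free energy, per-residue decomposition, hotspot detection), and
    prioritises point mutants for affinity maturation, including consensus
    double and triple mutants. Ships seeded synthetic-data generators so
    every stage is testable without external modelling tools.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
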