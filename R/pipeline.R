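#' Default pipeline configuration
#'
#' One declarative configuration for the whole design funnel. Every
#' stage threshold carries its conventional default: identity window
#' 0.75-0.90 to wild-type ubiquitin, length window 72-84, pLDDT floor 50,
#' contact cutoff 10 Angstrom, diversity radius 2 Angstrom, 50 kept
#' poses, top-50/top-10 energy means, hotspot threshold -2 kcal/mol and
#' maturation clustering at 97.5 percent identity.
#'
#' @param seed Global seed propagated (stably derived) to every
#'   stochastic stage.
#' @param outdir Output directory for stage reports and artifacts.
#' @return A nested list of class \code{"pipeline_config"}; override any
#'   entry by passing a partial list to \code{\link{run_pipeline}}.
#' @export
pipeline_config <- function(seed = 1L, outdir = "ubinder_run") {
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    stages = c("curate", "train", "generate", "filter", "triage",
               "energetics", "maturate"),
    curate = list(library_size = 759L, monomer_count = 329L,
                  dedup_identity = 0.99),
    train = list(max_len = 164L, encoder_lstm_units = 256L,
                 encoder_fc_units = 128L, latent_dim = 128L,
                 decoder_lstm_units = 256L, learning_rate = 0.001,
                 max_epochs = 200L, early_stop_patience = 5L,
                 batch_size = 64L),
    generate = list(n_sequences = 500L, temperature = 1.0),
    filter = list(identity_min = 0.75, identity_max = 0.90,
                  length_min = 72L, length_max = 84L, plddt_floor = 50),
    triage = list(contact_cutoff = 10, diversity_rmsd = 2,
                  max_kept_poses = 50L, docking_top_k = 50L,
                  pele_top_k = 10L, pose_deck_size = 60L,
                  max_candidates = 12L),
    energetics = list(n_frames = 500L, hotspot_threshold = -2,
                      band_fractions = c(1, 1, 1) / 3),
    maturate = list(cluster_identity = 0.975, pool_size = 100L,
                    max_consensus_order = 3L)
  ), class = "pipeline_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

write_stage_report <- function(outdir, stage, df) {
  path <- file.path(outdir, paste0(stage, "_report.tsv"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the design funnel end to end on synthetic fixtures
#'
#' Chains the pipeline stages — library curation, generator training, de
#' novo generation, sequence/structure-quality filtering, docking-pose
#' triage, energetic post-processing and mutant prioritisation — from a
#' single declarative configuration, writing one TSV report per stage
#' plus a funnel summary counting survivors. Reruns with an identical
#' configuration and seed produce byte-identical reports. A failing
#' stage aborts with an error naming the stage.
#'
#' @param config A \code{\link{pipeline_config}}, a partial list merged
#'   over the defaults, or the path to a YAML file holding such a list.
#' @param quiet Suppress per-stage progress messages (default FALSE).
#' @return Invisibly, a list with per-stage results and the funnel
#'   summary data frame.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "pipeline_config"))
    config <- merge_config(pipeline_config(), config)
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[ubinder] ", ...)
  funnel <- data.frame(stage = character(0), n_in = integer(0),
                       n_out = integer(0))
  note <- function(stage, n_in, n_out)
    funnel <<- rbind(funnel, data.frame(stage = stage, n_in = n_in,
                                        n_out = n_out))
  run_stage <- function(stage, fn) {
    if (!stage %in% cfg$stages) return(NULL)
    say("stage: ", stage)
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  res <- list()

  res$curate <- run_stage("curate", function() {
    fx <- fixture_config(seed = derive_seed(cfg$seed, 1L),
                         library_size = cfg$curate$library_size,
                         monomer_count = cfg$curate$monomer_count,
                         class_marginals =
                           scaled_class_marginals(cfg$curate$library_size))
    lib <- make_library(fx)
    mono <- split_dimers(lib)
    dcfg <- dataset_config(dedup_identity = cfg$curate$dedup_identity)
    dedup <- deduplicate(mono, dcfg)
    write_seq_library(dedup, file.path(cfg$outdir, "curated.fasta"))
    write_stage_report(cfg$outdir, "curate", data.frame(
      metric = c("library_records", "monomer_records", "deduplicated",
                 "seed"),
      value = c(nrow(lib), nrow(mono), nrow(dedup), fx$seed)))
    note("curate", nrow(lib), nrow(dedup))
    dedup
  })

  res$model <- run_stage("train", function() {
    tc <- cfg$train
    vc <- vae_config(encoder_lstm_units = tc$encoder_lstm_units,
                     encoder_fc_units = tc$encoder_fc_units,
                     latent_dim = tc$latent_dim,
                     decoder_state_units = tc$decoder_lstm_units,
                     decoder_lstm_units = tc$decoder_lstm_units,
                     learning_rate = tc$learning_rate,
                     max_epochs = tc$max_epochs,
                     early_stop_patience = tc$early_stop_patience,
                     batch_size = tc$batch_size,
                     seed = derive_seed(cfg$seed, 2L))
    model <- vae_fit(res$curate, vc, encoding_spec(tc$max_len))
    write_history_csv(model, file.path(cfg$outdir, "training_history.csv"))
    h <- model$history
    write_stage_report(cfg$outdir, "train", data.frame(
      metric = c("epochs", "best_epoch", "first_recon", "final_recon",
                 "final_kl", "seed"),
      value = c(nrow(h), model$best_epoch, h$recon[1], h$recon[nrow(h)],
                h$kl[nrow(h)], vc$seed)))
    note("train", nrow(res$curate), nrow(res$curate))
    model
  })

  res$generated <- run_stage("generate", function() {
    gc <- generation_config(cfg$generate$n_sequences,
                            cfg$generate$temperature,
                            seed = derive_seed(cfg$seed, 3L))
    seqs <- vae_generate(res$model, gc)
    seqs <- seqs[nchar(seqs) > 0]
    names(seqs) <- sprintf("gen_%04d", seq_along(seqs))
    write_seq_library(seq_records(names(seqs), seqs),
                      file.path(cfg$outdir, "generated.fasta"))
    write_stage_report(cfg$outdir, "generate", data.frame(
      metric = c("requested", "non_empty", "temperature", "seed"),
      value = c(cfg$generate$n_sequences, length(seqs),
                cfg$generate$temperature, gc$seed)))
    note("generate", cfg$generate$n_sequences, length(seqs))
    seqs
  })

  res$filtered <- run_stage("filter", function() {
    fc <- filter_config(cfg$filter$identity_min, cfg$filter$identity_max,
                        cfg$filter$length_min, cfg$filter$length_max,
                        cfg$filter$plddt_floor)
    fg <- filter_generated(res$generated, fc)
    kept <- fg$kept
    names(kept) <- fg$report$id[fg$report$kept]
    # synthetic model-confidence tracks for the sequence survivors
    if (length(kept) > 0L) {
      n_fail <- max(0L, round(length(kept) * 11 / 112))
      pl <- make_plddt_tracks(
        fixture_config(seed = derive_seed(cfg$seed, 4L),
                       plddt_fail_count = min(n_fail, length(kept))),
        n = length(kept))
      pf <- plddt_filter(pl$models, fc$plddt_floor)
      kept2 <- kept[pf$report$kept]
    } else {
      pf <- list(report = data.frame(id = character(0),
                                     min_plddt = numeric(0),
                                     mean_plddt = numeric(0),
                                     kept = logical(0)))
      kept2 <- kept
    }
    rep1 <- fg$report
    names(rep1)[names(rep1) == "kept"] <- "kept_seq_filter"
    write_stage_report(cfg$outdir, "filter", rep1)
    write_stage_report(cfg$outdir, "plddt", pf$report)
    note("filter", length(res$generated), length(kept))
    note("plddt", length(kept), length(kept2))
    kept2
  })

  res$triage <- run_stage("triage", function() {
    tc <- cfg$triage
    tri <- triage_config(tc$contact_cutoff, tc$diversity_rmsd,
                         tc$max_kept_poses, tc$docking_top_k,
                         tc$pele_top_k)
    cand <- res$filtered
    if (length(cand) > tc$max_candidates)
      cand <- cand[seq_len(tc$max_candidates)]
    if (length(cand) == 0L) stop("no candidates reached pose triage")
    rows <- lapply(seq_along(cand), function(i) {
      fx <- fixture_config(seed = derive_seed(cfg$seed, 100L + i),
                           pose_deck_size = tc$pose_deck_size)
      deck <- make_pose_deck(fx, tri)$deck
      rp <- interface_patch("receptor", 1:20, chain = "A")
      lp <- interface_patch("ligand", 1:12, chain = "B")
      kept_ifc <- interface_filter(deck, rp, lp, tri)
      clustered <- greedy_diverse_top(kept_ifc, tri)
      scores <- vapply(clustered$poses, `[[`, 0, "score")
      data.frame(candidate = names(cand)[i],
                 n_poses = length(deck$poses),
                 n_interface = length(kept_ifc$poses),
                 n_clustered = length(clustered$poses),
                 mean_top_docking = mean_top_k(scores, tri$docking_top_k),
                 mean_top_refine = mean_top_k(scores, tri$pele_top_k))
    })
    tab <- do.call(rbind, rows)
    dock <- stats::setNames(tab$mean_top_docking, tab$candidate)
    sel1 <- funnel_select(dock)
    refine <- stats::setNames(tab$mean_top_refine, tab$candidate)
    refine <- refine[sel1$kept]
    sel2 <- funnel_select(refine)
    tab$kept_docking <- tab$candidate %in% sel1$kept
    tab$kept_refine <- tab$candidate %in% sel2$kept
    write_stage_report(cfg$outdir, "triage", tab)
    note("triage_docking", length(cand), length(sel1$kept))
    note("triage_refine", length(sel1$kept), length(sel2$kept))
    list(table = tab, kept = sel2$kept,
         sequences = cand[sel2$kept])
  })

  res$energetics <- run_stage("energetics", function() {
    ec <- energetics_config(cfg$energetics$hotspot_threshold,
                            cfg$energetics$n_frames,
                            cfg$energetics$band_fractions)
    kept <- res$triage$kept
    if (length(kept) == 0L) stop("no candidates reached energetics")
    dg <- vapply(seq_along(kept), function(i) {
      planted <- with_seed(derive_seed(cfg$seed, 200L + i),
                           stats::rnorm(1, -30, 8))
      frames <- make_energy_frames(derive_seed(cfg$seed, 300L + i),
                                   cfg$energetics$n_frames, planted, 3)
      binding_dg(frames)$dG
    }, 0)
    names(dg) <- kept
    tab <- data.frame(candidate = kept, dG = as.numeric(dg),
                      stringsAsFactors = FALSE)
    if (length(dg) >= 3L) {
      bands <- band_candidates(dg, ec)
      tab <- merge(tab, bands[, c("candidate", "band")], by = "candidate",
                   sort = TRUE)
    } else {
      tab$band <- NA_character_
    }
    tab <- tab[order(tab$dG), ]
    write_stage_report(cfg$outdir, "energetics", tab)
    note("energetics", length(kept), nrow(tab))
    tab
  })

  res$maturation <- run_stage("maturate", function() {
    mc <- maturation_config(cfg$maturate$cluster_identity,
                            cfg$maturate$pool_size,
                            cfg$maturate$max_consensus_order)
    en <- res$energetics
    best <- en$candidate[which.min(en$dG)]
    parent <- res$triage$sequences[[best]]
    pool <- with_seed(derive_seed(cfg$seed, 5L), {
      vapply(seq_len(mc$n_generated_per_hit), function(i) {
        nm <- sample(1:4, 1)
        sp <- sample(nchar(parent), nm)
        ch <- strsplit(parent, "")[[1]]
        repl <- vapply(sp, function(p)
          sample(setdiff(AA_ALPHABET, ch[p]), 1), "")
        ch[sp] <- repl
        paste(ch, collapse = "")
      }, "")
    })
    cl <- cluster_pool(pool, mc)
    specs <- lapply(cl$centroids, diff_mutations, parent = parent,
                    parent_id = best)
    specs <- specs[vapply(specs, function(s) length(s$position) > 0, NA)]
    singles <- enumerate_singles(specs)
    sdg <- with_seed(derive_seed(cfg$seed, 6L),
                     round(stats::runif(length(singles), -3, 2), 3))
    cons <- if (length(singles) >= 2L)
      consensus_mutants(singles, sdg, mc) else list()
    tab <- data.frame(
      mutation = vapply(singles, format_mutations, ""),
      ddG = sdg, stringsAsFactors = FALSE)
    write_stage_report(cfg$outdir, "maturate", tab)
    write_stage_report(cfg$outdir, "consensus", data.frame(
      mutant = vapply(cons, format_mutations, character(1))))
    note("maturate_singles", length(cl$centroids), length(singles))
    note("maturate_consensus", length(singles), length(cons))
    list(parent = best, clusters = cl, singles = singles, ddg = sdg,
         consensus = cons)
  })

  write_stage_report(cfg$outdir, "funnel_summary", funnel)
  say("done: ", cfg$outdir)
  invisible(c(res, list(funnel = funnel, config = cfg)))
}
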