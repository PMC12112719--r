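test_that("binder classification partitions K_D and matches the banded panels", {
  expect_equal(classify_binder(5.4), "SB")
  expect_equal(classify_binder(29.8), "MB")
  expect_equal(classify_binder(100.0), "WB")
  expect_equal(classify_binder(10.0), "MB")   # half-open on the strong side
  expect_equal(classify_binder(9.999), "SB")
  # every positive kd maps to exactly one class, monotone in kd
  grid <- c(0.01, 0.1, 1, 9.99, 10, 50, 99.99, 100, 1e3, 1e5)
  cls <- classify_binder(grid)
  expect_true(all(cls %in% c("SB", "MB", "WB")))
  rank <- match(cls, c("SB", "MB", "WB"))
  expect_true(all(diff(rank) >= 0))
  expect_error(classify_binder(0), "positive")
  expect_error(classify_binder(c(1, NA)), "positive")
})

test_that("dimer splitting cuts at the leftmost internal motif and conserves residues", {
  cfg <- dataset_config()
  wt <- ubiquitin_wt()

  # motif only at position 1: unchanged
  r <- seq_records("mono", wt)
  out <- split_dimer(r, cfg)
  expect_equal(nrow(out), 1L)
  expect_equal(out$sequence, wt)

  # two 80-mers concatenated, junction led by MRI
  m1 <- paste0(wt, "AAAG")                       # 80 aa, starts MQI
  m2 <- paste0("MRI", substr(paste0(wt, "AAAG"), 4, 80))
  expect_equal(nchar(m2), 80L)
  dim160 <- paste0(m1, m2)
  out <- split_dimer(seq_records("dim", dim160), cfg)
  expect_equal(nrow(out), 2L)
  expect_equal(nchar(out$sequence), c(80L, 80L))
  expect_equal(paste0(out$sequence[1], out$sequence[2]), dim160)
  expect_equal(substr(out$sequence[2], 1, 3), "MRI")

  # internal motifs at positions 81 and 121: split at 81 only
  tail40 <- paste0("MAS", substr(wt, 4, 40))
  triple <- paste0(m1, substr(m2, 1, 40), tail40)
  out <- split_dimer(seq_records("tri", triple), cfg)
  expect_equal(nrow(out), 2L)
  expect_equal(nchar(out$sequence[1]), 80L)
  expect_equal(paste0(out$sequence[1], out$sequence[2]), triple)

  expect_error(split_dimer(list(id = "x", sequence = ""), cfg), "non-empty")
})

test_that("splitting a fixture library conserves residues record by record", {
  lib <- small_library(seed = 3L)
  for (i in seq_len(nrow(lib))) {
    out <- split_dimer(lib[i, ])
    expect_equal(paste(out$sequence, collapse = ""), lib$sequence[i])
  }
  mono <- split_dimers(lib)
  expect_true(all(nchar(mono$sequence) <= 84))
})

test_that("deduplication is greedy first-wins, order preserving and idempotent", {
  wt <- ubiquitin_wt()
  cfg <- dataset_config()

  # byte-identical pair collapses
  recs <- seq_records(c("a", "b"), c(wt, wt))
  expect_equal(nrow(deduplicate(recs, cfg)), 1L)
  expect_equal(deduplicate(recs, cfg)$id, "a")

  # one substitution in 76: identity 75/76 < 0.99, both kept
  set.seed(5)
  v <- substitute_k(wt, 1)
  recs <- seq_records(c("a", "b"), c(wt, v))
  expect_equal(nrow(deduplicate(recs, cfg)), 2L)

  # empty input passes through
  expect_equal(nrow(deduplicate(recs[0, ], cfg)), 0L)

  # idempotence and order preservation on a fixture library
  lib <- small_library(seed = 9L)
  once <- deduplicate(lib, cfg)
  twice <- deduplicate(once, cfg)
  expect_identical(once$sequence, twice$sequence)
  expect_identical(once$id, lib$id[lib$id %in% once$id])
})

test_that("deduplication fast paths agree with the all-pairs alignment route", {
  naive_dedup <- function(records, thr) {
    kept <- integer(0)
    for (i in seq_len(nrow(records))) {
      dup <- any(vapply(kept, function(j)
        pairwise_identity(records$sequence[i], records$sequence[j]) >= thr,
        NA))
      if (!dup) kept <- c(kept, i)
    }
    records$id[kept]
  }
  set.seed(21)
  wt <- ubiquitin_wt()
  pool <- c(wt, wt, substitute_k(wt, 1), substitute_k(wt, 3),
            substr(wt, 1, 75), random_seq(76), random_seq(80))
  recs <- seq_records(sprintf("s%d", seq_along(pool)), pool)
  for (thr in c(0.95, 0.99, 1.0)) {
    cfg <- dataset_config(dedup_identity = thr)
    expect_identical(deduplicate(recs, cfg)$id, naive_dedup(recs, thr),
                     info = paste("threshold", thr))
  }
})

test_that("FASTA round trip preserves sequences and key=value annotations", {
  recs <- seq_records(c("v1", "v2", "v3"),
                      c(ubiquitin_wt(), substitute_k(ubiquitin_wt(), 2),
                        random_seq(80)),
                      kd_nM = c(5.4, NA, 250),
                      target = c("HER3", NA, "HER2"),
                      binder_class = c("SB", NA, "WB"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_seq_library(recs, path)
  back <- read_seq_library(path)
  expect_equal(back$id, recs$id)
  expect_equal(back$sequence, recs$sequence)
  expect_equal(back$kd_nM, recs$kd_nM)
  expect_equal(back$target, recs$target)
  expect_equal(back$class, recs$class)
  # wrapped at 60 columns
  expect_true(all(nchar(readLines(path)) <= 60))
})

test_that("record validation rejects bad alphabets, classes and kd values", {
  expect_error(seq_records("x", "MQIFZ"), "invalid letters")
  expect_error(seq_records("x", "MQIF", kd_nM = -1), "positive")
  expect_error(seq_records("x", "MQIF", binder_class = "XX"), "class")
  expect_silent(seq_records("x", "MQIF", binder_class = "NB"))
})
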