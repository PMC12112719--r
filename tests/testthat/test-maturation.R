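test_that("pool clustering is greedy with an inclusive identity boundary", {
  set.seed(15)
  parent <- random_seq(80)

  # identical pool collapses to one cluster
  cl <- cluster_pool(rep(parent, 5))
  expect_equal(length(cl$centroids), 1L)
  expect_equal(cl$assignment, rep(1L, 5))

  # 4-substitution variants of an 80-mer: 76/80 = 0.95 < 0.975, singletons
  far <- vapply(1:3, function(i) substitute_k(parent, 4), "")
  cl <- cluster_pool(c(parent, far))
  expect_equal(length(cl$centroids), 4L)

  # 2-substitution variant: 78/80 = 0.975 joins at the boundary
  near <- substitute_k(parent, 2)
  cl <- cluster_pool(c(parent, near))
  expect_equal(length(cl$centroids), 1L)
  expect_equal(cl$centroids, parent)  # centroid is the first member

  expect_error(cluster_pool(character(0)), "empty")
})

test_that("every pool member lands in exactly one cluster near its centroid", {
  set.seed(16)
  parent <- random_seq(80)
  pool <- c(parent,
            vapply(1:12, function(i) substitute_k(parent, sample(1:6, 1)), ""))
  cl <- cluster_pool(pool)
  expect_equal(sort(unname(unlist(cl$clusters))), seq_along(pool))
  for (k in seq_along(cl$clusters)) {
    for (i in cl$clusters[[k]]) {
      expect_gte(pairwise_identity(pool[i], cl$centroids[k]), 0.975)
    }
  }
  expect_lte(length(cl$centroids), length(pool))
})

test_that("mutation diffing recovers planted substitutions exactly", {
  set.seed(17)
  parent <- random_seq(76)
  expect_equal(length(diff_mutations(parent, parent)$position), 0L)

  # planted K6R + E7Q style double
  ch <- strsplit(parent, "")[[1]]
  v <- ch; v[6] <- setdiff(ubinder:::AA_ALPHABET, ch[6])[1]
  v[7] <- setdiff(ubinder:::AA_ALPHABET, ch[7])[1]
  spec <- diff_mutations(parent, paste(v, collapse = ""))
  expect_equal(spec$position, c(6L, 7L))
  expect_equal(spec$from, ch[6:7])

  # random 10-substitution fixture
  variant <- substitute_k(parent, 10)
  spec <- diff_mutations(parent, variant)
  expect_equal(length(spec$position), 10L)
  expect_equal(apply_mutant(parent, spec), variant)

  expect_error(diff_mutations(parent, substr(parent, 1, 70)), "length")
})

test_that("single-mutant enumeration unions and deduplicates substitutions", {
  parent <- "MKTAYIAKQR"
  s1 <- parse_mutations("K2R+T3A+Y5F", "p")
  s2 <- parse_mutations("K2R+A4G", "p")
  singles <- enumerate_singles(list(s1, s2))
  expect_equal(vapply(singles, format_mutations, ""),
               c("K2R", "T3A", "A4G", "Y5F"))   # position then residue order

  one <- enumerate_singles(list(s1))
  expect_length(one, 3L)

  # 12 multi-mutants carrying 27 distinct substitutions yield 27 singles
  set.seed(18)
  parent76 <- random_seq(76)
  pch <- strsplit(parent76, "")[[1]]
  pool_pos <- sample(76, 27)
  subs <- data.frame(position = pool_pos,
                     from = pch[pool_pos],
                     to = vapply(pool_pos, function(p)
                       sample(setdiff(ubinder:::AA_ALPHABET, pch[p]), 1), ""))
  specs <- lapply(1:12, function(i) {
    take <- subs[sample(27, sample(2:5, 1)), ]
    mutant_spec("p76", take$position, take$from, take$to)
  })
  # ensure full coverage by adding one spec containing the rest
  seen <- unique(unlist(lapply(specs, `[[`, "position")))
  rest <- subs[!subs$position %in% seen, ]
  if (nrow(rest))
    specs <- c(specs, list(mutant_spec("p76", rest$position, rest$from,
                                       rest$to)))
  expect_length(enumerate_singles(specs), 27L)
})

test_that("consensus mutants combine improving, position-compatible singles", {
  mk <- function(s) parse_mutations(s, "p")
  singles <- list(mk("K6R"), mk("E7Q"), mk("T9A"))
  cons <- consensus_mutants(singles, c(-2.1, -1.0, 0.5))
  expect_equal(vapply(cons, format_mutations, ""), "K6R+E7Q")

  # two improving singles at the same position never combine
  cons2 <- consensus_mutants(list(mk("K6R"), mk("K6N")), c(-2, -1))
  expect_length(cons2, 0L)

  # three improving singles at distinct positions: 3 doubles + 1 triple
  cons3 <- consensus_mutants(list(mk("K6R"), mk("E7Q"), mk("T9A")),
                             c(-2.1, -1.0, -0.4))
  expect_length(cons3, 4L)
  orders <- vapply(cons3, function(s) length(s$position), 0L)
  expect_equal(sort(orders), c(2L, 2L, 2L, 3L))
  # each component of each consensus mutant is improving and positions unique
  for (cs in cons3) expect_false(anyDuplicated(cs$position) > 0)

  expect_length(consensus_mutants(list(mk("K6R"), mk("E7Q")), c(0.2, 1)), 0L)
  expect_error(consensus_mutants(list(mk("K6R")), -1), "at least 2")
})

test_that("applying mutants is consistent with diffing and validates residues", {
  parent <- "MKTAYIAKQR"
  expect_equal(apply_mutant(parent, mutant_spec("p")), parent)

  spec <- parse_mutations("K2R", "p")
  mutated <- apply_mutant(parent, spec)
  expect_equal(substr(mutated, 2, 2), "R")
  expect_equal(diff_mutations(parent, mutated)$position, 2L)

  # round trip: apply then diff recovers the spec
  set.seed(19)
  p76 <- random_seq(76)
  v <- substitute_k(p76, 6)
  spec <- diff_mutations(p76, v)
  expect_equal(format_mutations(diff_mutations(p76, apply_mutant(p76, spec))),
               format_mutations(spec))

  expect_error(apply_mutant(parent, parse_mutations("A2R", "p")),
               "mismatch")
  expect_error(apply_mutant(parent, parse_mutations("K99R", "p")),
               "outside")
})

test_that("mutation strings and scored-singles files round trip", {
  expect_equal(format_mutations(parse_mutations("K6R+E7Q")), "K6R+E7Q")
  expect_equal(format_mutations(parse_mutations("WT")), "WT")
  expect_error(parse_mutations("K6"), "malformed")

  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(mutation = c("K6R", "E7Q"),
                                ddG = c(-2.1, 0.3)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  sc <- read_scored_singles(path, "hit1")
  expect_equal(vapply(sc$singles, format_mutations, ""), c("K6R", "E7Q"))
  expect_equal(sc$ddg, c(-2.1, 0.3))
})
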