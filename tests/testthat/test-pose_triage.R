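# Three-residue strip whose Calpha atoms sit on a line along x, placed so
# the closest receptor/ligand patch atoms are exactly `gap` apart.
strip <- function(chain, x0, gap_axis = 0) {
  ca_structure(chain = chain, resno = 1:3, resname = "GLY",
               xyz = cbind(x0 + c(0, 1, 2), 0, gap_axis))
}

test_that("interface filtering is a closed-form 10 A proximity decision", {
  rec <- strip("A", 0)
  cfg <- triage_config()
  rp <- interface_patch("receptor", 1:3)
  lp <- interface_patch("ligand", 1:3)
  mk <- function(id, dist) pose(id, rec, strip("B", 2 + dist), -10)

  deck <- pose_deck(list(mk("near", 9.9), mk("at", 10.0), mk("far", 10.1)))
  kept <- interface_filter(deck, rp, lp, cfg)
  expect_setequal(vapply(kept$poses, `[[`, "", "id"), c("near", "at"))

  # raising the cutoff never shrinks the kept set
  kept_wide <- interface_filter(deck, rp, lp, triage_config(contact_cutoff = 12))
  expect_true(all(vapply(kept$poses, `[[`, "", "id") %in%
                    vapply(kept_wide$poses, `[[`, "", "id")))

  # unknown patch residues are an error
  expect_error(interface_filter(deck, interface_patch("receptor", 99), lp, cfg),
               "absent")
})

test_that("poses touching only an exclusion patch are discarded", {
  # receptor with two regions: the true epitope (residues 1-3, at x ~ 0)
  # and an exclusion area (residues 11-13, at x ~ 30)
  rec <- ca_structure(chain = "A", resno = c(1:3, 11:13), resname = "GLY",
                      xyz = cbind(c(0, 1, 2, 30, 31, 32), 0, 0))
  rp <- interface_patch("receptor", 1:3)
  lp <- interface_patch("ligand", 1:3)
  near_epitope <- pose("good", rec, strip("B", 8), -10)
  near_exclusion <- pose("bad", rec, strip("B", 26), -12)
  deck <- pose_deck(list(near_epitope, near_exclusion))

  no_excl <- interface_filter(deck, rp, lp, triage_config())
  expect_equal(length(no_excl$poses), 1L)  # "bad" is 16 A from the epitope

  cfg <- triage_config(exclusion_patch = interface_patch("receptor", 11:13))
  # widen epitope so "bad" would pass proximity, then exclusion removes it
  rp_all <- interface_patch("receptor", c(1:3, 11:13))
  kept <- interface_filter(deck, rp_all, lp, cfg)
  expect_equal(vapply(kept$poses, `[[`, "", "id"), "good")
})

test_that("greedy clustering keeps low-energy mutually diverse poses", {
  rec <- test_mini(12, "A")
  lig <- test_mini(6, "B", origin = c(10, 0, 5))
  at <- function(id, dx, score)
    pose(id, rec, move_st(lig, trans = c(dx, 0, 0)), score)

  # hand trace: P2 is 1.5 A from P1 and dropped; P3 is ~5 A from both
  deck <- pose_deck(list(at("P1", 0, -30), at("P2", 1.5, -29),
                         at("P3", 5, -28)))
  kept <- greedy_diverse_top(deck, triage_config())
  expect_equal(vapply(kept$poses, `[[`, "", "id"), c("P1", "P3"))

  # 4 mutually distant poses are all kept, score ordered
  deck4 <- pose_deck(list(at("a", 0, -10), at("b", 9, -40),
                          at("c", 18, -20), at("d", 27, -30)))
  kept4 <- greedy_diverse_top(deck4, triage_config())
  expect_equal(vapply(kept4$poses, `[[`, "", "id"), c("b", "d", "c", "a"))

  # RMSD exactly at the radius is "not greater than 2 A": rejected
  deck_eq <- pose_deck(list(at("P1", 0, -30), at("Peq", 2, -29)))
  expect_equal(length(greedy_diverse_top(deck_eq, triage_config())$poses), 1L)

  # cap on kept poses respected
  capped <- greedy_diverse_top(deck4, triage_config(max_kept_poses = 2L))
  expect_equal(vapply(capped$poses, `[[`, "", "id"), c("b", "d"))
})

test_that("greedy clustering equals the brute-force reference on random decks", {
  for (seed in 1:6) {
    fx <- make_pose_deck(fixture_config(seed = seed, pose_deck_size = 40L))
    got <- greedy_diverse_top(fx$deck, triage_config())
    ids <- vapply(got$poses, `[[`, "", "id")
    expect_identical(ids, fx$truth_ids, info = paste("seed", seed))
    # kept poses are pairwise separated by more than the radius
    if (length(got$poses) > 1L) {
      for (i in 1:(length(got$poses) - 1))
        for (j in (i + 1):length(got$poses))
          expect_gt(ligand_rmsd(got$poses[[i]], got$poses[[j]]), 2)
    }
    # the global best pose is always kept
    scores <- vapply(fx$deck$poses, `[[`, 0, "score")
    best <- vapply(fx$deck$poses, `[[`, "", "id")[which.min(scores)]
    expect_true(best %in% ids)
  }
})

test_that("top-k energy means follow direct arithmetic", {
  expect_equal(mean_top_k(c(-5, -4, -3), 2), -4.5)
  expect_equal(mean_top_k(c(-5, -4, -3), 10), -4)   # fewer than k: plain mean
  set.seed(14)
  scores <- rnorm(120, -20, 5)
  expect_equal(mean_top_k(scores, 50), mean(sort(scores)[1:50]))
  expect_error(mean_top_k(numeric(0), 5), "no scores")
})

test_that("funnel selection discards candidates above the cross-system mean", {
  sel <- funnel_select(c(A = -10, B = -20, C = -30))
  expect_equal(sel$mean, -20)
  expect_setequal(sel$kept, c("B", "C"))   # exactly at the mean survives

  all_equal <- funnel_select(c(a = -5, b = -5, c = -5))
  expect_setequal(all_equal$kept, c("a", "b", "c"))

  expect_equal(funnel_select(c(only = -1))$kept, "only")

  # the argmin candidate is always kept
  set.seed(9)
  for (rep in 1:10) {
    sc <- rnorm(sample(2:12, 1))
    names(sc) <- sprintf("c%d", seq_along(sc))
    sel <- funnel_select(sc)
    expect_true(names(sc)[which.min(sc)] %in% sel$kept)
    expect_gte(length(sel$kept), 1L)
  }
})

test_that("patch files parse chain:index residue lists", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# epitope", "A:17", "A:21", "A:22"), path)
  p <- read_patch(path, "receptor")
  expect_equal(p$residues, c(17L, 21L, 22L))
  expect_equal(p$chain, "A")
  expect_equal(p$role, "receptor")
})
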