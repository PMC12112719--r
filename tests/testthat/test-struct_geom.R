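test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(8)
  pts <- matrix(rnorm(30), 10, 3)
  id <- kabsch_superpose(pts, pts)
  expect_equal(id$rmsd, 0, tolerance = 1e-9)
  expect_equal(id$rotation, diag(3), tolerance = 1e-9)
  expect_equal(id$translation, c(0, 0, 0), tolerance = 1e-9)

  rot <- rotation_about(c(1, 2, 3), 0.9)
  moved <- sweep(pts %*% rot, 2, c(4, -2, 7), `+`)
  fit <- kabsch_superpose(pts, moved)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)  # no reflection

  expect_error(kabsch_superpose(pts[1:2, ], pts[1:2, ]), "3 points")
})

test_that("Kabsch RMSD matches a rotation-grid search on a 3-point toy", {
  a <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  b <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 1))
  got <- kabsch_superpose(a, b)$rmsd

  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  grid_rmsd <- function(par) {
    R <- rotation_about(c(cos(par[1]) * sin(par[2]),
                          sin(par[1]) * sin(par[2]),
                          cos(par[2])), par[3])
    sqrt(mean(rowSums((ac %*% R - bc)^2)))
  }
  best <- Inf
  for (th in seq(0, 2 * pi, length.out = 25))
    for (ph in seq(0, pi, length.out = 13))
      for (an in seq(0, 2 * pi, length.out = 25)) {
        o <- stats::optim(c(th, ph, an), grid_rmsd,
                          method = "Nelder-Mead")$value
        if (o < best) best <- o
      }
  expect_equal(got, best, tolerance = 1e-3)
  expect_lte(got, best + 1e-9)  # Kabsch is never beaten by the grid
})

test_that("superposed RMSD never exceeds unsuperposed RMSD", {
  set.seed(12)
  for (rep in 1:10) {
    a <- matrix(rnorm(24), 8, 3)
    b <- a + matrix(rnorm(24, sd = 0.5), 8, 3)
    expect_lte(kabsch_superpose(a, b)$rmsd,
               sqrt(mean(rowSums((a - b)^2))) + 1e-9)
  }
})

test_that("alignment-guided Ca RMSD handles self, rigid copies and homologs", {
  s <- test_mini(20)
  s$resname <- rep(c("ALA", "GLY", "LEU", "SER"), 5)
  expect_equal(aligned_ca_rmsd(s, s), 0, tolerance = 1e-9)

  moved <- move_st(s, rotation_about(c(0, 0, 1), 1.2), c(5, 5, -3))
  expect_lt(aligned_ca_rmsd(s, moved), 1e-6)

  # same sequence, one displaced residue: equals direct Kabsch on the
  # hand-matched (positional) pairs
  bent <- s
  bent$z[10] <- bent$z[10] + 2
  direct <- kabsch_superpose(ubinder:::st_xyz(s), ubinder:::st_xyz(bent))$rmsd
  expect_equal(aligned_ca_rmsd(s, bent), direct, tolerance = 1e-9)
  expect_gt(direct, 0)
})

test_that("ligand RMSD reflects pure translations and is frame invariant", {
  rec <- test_mini(12, "A")
  lig <- test_mini(6, "B", origin = c(10, 0, 5))
  p <- pose("p", rec, lig, -30)
  expect_equal(ligand_rmsd(p, p), 0, tolerance = 1e-9)

  # ligand translated 3 A along x, receptors identical
  q <- pose("q", rec, move_st(lig, trans = c(3, 0, 0)), -28)
  expect_equal(ligand_rmsd(p, q), 3.0, tolerance = 1e-6)

  # moving q's receptor AND ligand rigidly together changes nothing
  rot <- rotation_about(c(1, 1, 0), 0.7)
  q2 <- pose("q2", move_st(rec, rot, c(-4, 2, 9)),
             move_st(move_st(lig, trans = c(3, 0, 0)), rot, c(-4, 2, 9)),
             -28)
  expect_equal(ligand_rmsd(p, q2), 3.0, tolerance = 1e-6)

  # whole-pose rigid copy of p is at RMSD 0
  p2 <- pose("p2", move_st(rec, rot, c(1, 2, 3)),
             move_st(lig, rot, c(1, 2, 3)), -30)
  expect_lt(ligand_rmsd(p, p2), 1e-6)
})

test_that("ligand RMSD is symmetric and rejects mismatched compositions", {
  set.seed(3)
  rec <- test_mini(12, "A")
  for (rep in 1:5) {
    l1 <- move_st(test_mini(6, "B", origin = c(10, 0, 5)),
                  rotation_about(rnorm(3), runif(1, 0, 1)), rnorm(3, 0, 3))
    l2 <- move_st(test_mini(6, "B", origin = c(10, 0, 5)),
                  rotation_about(rnorm(3), runif(1, 0, 1)), rnorm(3, 0, 3))
    p <- pose("a", rec, l1, 0); q <- pose("b", rec, l2, 0)
    expect_equal(ligand_rmsd(p, q), ligand_rmsd(q, p), tolerance = 1e-6)
  }
  bad <- pose("c", rec, test_mini(5, "B"), 0)
  expect_error(ligand_rmsd(pose("a", rec, test_mini(6, "B"), 0), bad),
               "mismatched ligand")
})

test_that("trajectory ligand RMSD reports planted drift exactly", {
  rec <- test_mini(12, "A")
  lig <- test_mini(6, "B", origin = c(10, 0, 5))
  ref <- pose("ref", rec, lig, 0)

  frames_same <- lapply(1:4, function(i) ref)
  expect_equal(trajectory_lrmsd(frames_same, ref)$series, rep(0, 4),
               tolerance = 1e-9)

  one_shift <- list(ref, pose("f", rec, move_st(lig, trans = c(0, 2, 0)), 0))
  expect_equal(trajectory_lrmsd(one_shift, ref)$max, 2, tolerance = 1e-6)

  # linear drift: frame t translated t * (0.5, 0, 0)
  drift <- lapply(1:5, function(t)
    pose(paste0("f", t), rec, move_st(lig, trans = c(0.5 * t, 0, 0)), 0))
  res <- trajectory_lrmsd(drift, ref)
  expect_equal(res$series, 0.5 * (1:5), tolerance = 1e-6)
  expect_equal(res$mean, mean(0.5 * (1:5)), tolerance = 1e-6)
})

test_that("structures round trip through PDB files", {
  s <- test_mini(8, "A", origin = c(1, 2, 3))
  s$plddt <- seq(60, 95, length.out = 8)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "m.pdb")
  write_ca_structure(s, path)
  back <- read_ca_structure(path)
  expect_equal(back$resno, s$resno)
  expect_equal(back$chain, s$chain)
  expect_equal(back$x, s$x, tolerance = 1e-3)
  expect_equal(back$z, s$z, tolerance = 1e-3)
  expect_equal(back$plddt, s$plddt, tolerance = 1e-2)

  # pose decks round trip with manifest scores
  lig <- test_mini(5, "B", origin = c(8, 0, 4))
  deck <- pose_deck(list(pose("p1", s, lig, -20.5),
                         pose("p2", s, move_st(lig, trans = c(3, 0, 0)), -18)))
  ddir <- file.path(dir, "deck")
  write_pose_deck(deck, ddir)
  back_deck <- read_pose_deck(ddir)
  expect_equal(vapply(back_deck$poses, `[[`, "", "id"), c("p1", "p2"))
  expect_equal(vapply(back_deck$poses, `[[`, 0, "score"), c(-20.5, -18))
  expect_equal(ligand_rmsd(back_deck$poses[[1]], back_deck$poses[[2]]), 3,
               tolerance = 1e-3)
})
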