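# Shared helpers for the test suite. All fixtures are built in code.

# Random valid amino-acid sequence.
random_seq <- function(n) paste(sample(ubinder:::AA_ALPHABET, n, replace = TRUE),
                                collapse = "")

# Substitute `k` random positions of `s` (never to the original residue).
substitute_k <- function(s, k, from = 1L) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(from:length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(ubinder:::AA_ALPHABET, ch[p]), 1)
  paste(ch, collapse = "")
}

# Small helical mini-protein used by geometry tests.
test_mini <- function(n, chain = "A", origin = c(0, 0, 0)) {
  t <- seq_len(n)
  xyz <- cbind(2.3 * cos(t * 100 * pi / 180),
               2.3 * sin(t * 100 * pi / 180),
               1.5 * t) + matrix(origin, n, 3, byrow = TRUE)
  ca_structure(chain = chain, resno = t, resname = "ALA", xyz = xyz)
}

# Rigid-motion helpers.
rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

move_st <- function(s, rot = diag(3), trans = c(0, 0, 0)) {
  xyz <- as.matrix(s[, c("x", "y", "z")]) %*% rot
  xyz <- sweep(xyz, 2, trans, `+`)
  s$x <- xyz[, 1]; s$y <- xyz[, 2]; s$z <- xyz[, 3]
  s
}

# A tiny scaffold library for fast sequence tests.
small_library <- function(seed = 11L, n = 40L, monomers = 25L) {
  marg <- matrix(round(default_class_marginals() * n / 759), 3, 3,
                 dimnames = dimnames(default_class_marginals()))
  marg[3, 3] <- marg[3, 3] + n - sum(marg)
  make_library(fixture_config(seed = seed, library_size = n,
                              monomer_count = monomers,
                              class_marginals = marg))
}

# Independent affine-gap (Gotoh) global aligner used as the alignment
# oracle: gap of length L costs open + L * extend, end gaps penalised.
# Returns the optimal identity (identical columns / alignment length)
# among optimal-score alignments via traceback.
oracle_identity <- function(a, b, open = 10, extend = 0.5) {
  sub <- ubinder:::get_sub_matrix("BLOSUM62")
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - extend * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -open - extend * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sc <- sub[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
    }
  }
  # traceback (prefer M, then X, then Y at ties)
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  matches <- 0L; cols <- 0L
  while (i > 1 || j > 1) {
    cols <- cols + 1L
    if (i == 1L) state <- 3L
    if (j == 1L) state <- 2L
    if (state == 1L) {
      if (A[i - 1] == B[j - 1]) matches <- matches + 1L
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      i <- i - 1; j <- j - 1
      state <- which.max(prev)
    } else if (state == 2L) {
      from_m <- M[i - 1, j] - open - extend
      from_x <- X[i - 1, j] - extend
      state <- if (from_m >= from_x) 1L else 2L
      i <- i - 1
    } else {
      from_m <- M[i, j - 1] - open - extend
      from_y <- Y[i, j - 1] - extend
      state <- if (from_m >= from_y) 1L else 3L
      j <- j - 1
    }
  }
  matches / cols
}
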