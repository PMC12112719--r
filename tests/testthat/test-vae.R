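# Small architectures keep these tests fast; the model code is identical
# at every width.
tiny_cfg <- function(seed = 1L, max_epochs = 15L, ...) {
  vae_config(encoder_lstm_units = 24L, encoder_fc_units = 12L,
             latent_dim = 6L, decoder_state_units = 24L,
             decoder_lstm_units = 24L, batch_size = 8L,
             learning_rate = 0.01, max_epochs = max_epochs,
             early_stop_patience = 5L, seed = seed, ...)
}

test_that("one-hot encoding is positional with a trailing padding block", {
  spec <- encoding_spec(164L)
  m <- one_hot_encode(ubiquitin_wt(), spec)
  expect_equal(dim(m), c(164L, 21L))
  expect_equal(rowSums(m), rep(1, 164))
  expect_equal(sum(m[1:76, 21]), 0)        # no padding inside the sequence
  expect_equal(sum(m[77:164, 21]), 88)     # 88 padding rows

  empty <- one_hot_encode("", spec)
  expect_equal(sum(empty[, 21]), 164)

  expect_error(one_hot_encode(random_seq(165), spec), "longer")
  expect_error(one_hot_encode("MQIX", spec), "invalid letters")
})

test_that("encoding round trips for arbitrary valid sequences", {
  spec <- encoding_spec(90L)
  set.seed(22)
  for (rep in 1:10) {
    s <- random_seq(sample(0:90, 1))
    expect_identical(one_hot_decode(one_hot_encode(s, spec), spec), s)
  }
})

test_that("training is seed deterministic and the ELBO decomposes validly", {
  set.seed(23)
  seqs <- vapply(1:12, function(i) substitute_k(ubiquitin_wt(), 10), "")
  spec <- encoding_spec(80L)
  fit1 <- vae_fit(seqs, tiny_cfg(seed = 5L, max_epochs = 4L), spec)
  fit2 <- vae_fit(seqs, tiny_cfg(seed = 5L, max_epochs = 4L), spec)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$params, fit2$params)

  # ELBO = reconstruction + KL, with KL non-negative at every epoch
  h <- fit1$history
  expect_equal(h$train_elbo, h$recon + h$kl, tolerance = 1e-9)
  expect_true(all(h$kl >= 0))

  expect_error(vae_fit(character(0), tiny_cfg()), "at least 2")
})

test_that("the generator memorizes a single repeated sequence", {
  peptide <- "MQIFVKTLTGKTITLEVEPSDTIE"   # short scaffold fragment
  spec <- encoding_spec(28L)
  cfg <- tiny_cfg(seed = 7L, max_epochs = 120L)
  fit <- vae_fit(rep(peptide, 30), cfg, spec)

  # learning-progress oracle
  h <- fit$history
  expect_lt(h$recon[nrow(h)], h$recon[1])

  # greedy decoding of the latent mean reproduces the sequence exactly
  mu <- predict(fit, peptide)$mu
  expect_identical(vae_decode(fit, mu, temperature = 1e-7), peptide)

  # near-zero temperature generation from any latent draw reproduces it too
  g <- vae_generate(fit, generation_config(5, temperature = 1e-7, seed = 42))
  expect_true(all(g == peptide))
})

test_that("generation is seed deterministic and alphabet valid", {
  set.seed(24)
  seqs <- vapply(1:16, function(i) substitute_k(ubiquitin_wt(), 8), "")
  fit <- vae_fit(seqs, tiny_cfg(seed = 3L, max_epochs = 6L),
                 encoding_spec(80L))

  g1 <- vae_generate(fit, generation_config(10, seed = 1L))
  g2 <- vae_generate(fit, generation_config(10, seed = 1L))
  expect_identical(g1, g2)
  g3 <- vae_generate(fit, generation_config(10, seed = 2L))
  expect_false(identical(g1, g3))
  expect_length(g1, 10L)

  # only the 20-residue alphabet, never the padding symbol
  letters_used <- unique(strsplit(paste(g1, collapse = ""), "")[[1]])
  expect_true(all(letters_used %in% ubinder:::AA_ALPHABET))

  expect_error(vae_generate(list(), generation_config(1)), "not a fitted")
})

test_that("checkpoints restore the generator bit-identically", {
  set.seed(25)
  seqs <- vapply(1:10, function(i) substitute_k(ubiquitin_wt(), 8), "")
  fit <- vae_fit(seqs, tiny_cfg(seed = 9L, max_epochs = 3L),
                 encoding_spec(80L))
  path <- withr::local_tempfile(fileext = ".rds")
  before <- vae_generate(fit, generation_config(8, seed = 6L))
  vae_save(fit, path)
  restored <- vae_load(path)
  expect_identical(vae_generate(restored, generation_config(8, seed = 6L)),
                   before)
  expect_identical(restored$params, fit$params)
})

test_that("model methods expose fit diagnostics", {
  set.seed(26)
  seqs <- vapply(1:10, function(i) substitute_k(ubiquitin_wt(), 8), "")
  fit <- vae_fit(seqs, tiny_cfg(seed = 2L, max_epochs = 3L),
                 encoding_spec(80L))
  expect_output(print(fit), "LSTM variational autoencoder")
  s <- summary(fit)
  expect_output(print(s), "reconstruction loss")
  expect_equal(s$epochs, nrow(fit$history))
  expect_named(coef(fit), names(ubinder:::vae_init_params(fit$config)))
  sim <- simulate(fit, nsim = 3, seed = 11)
  expect_identical(sim, vae_generate(fit, generation_config(3, 1.0, 11L)))
  hist_csv <- withr::local_tempfile(fileext = ".csv")
  write_history_csv(fit, hist_csv)
  expect_equal(nrow(utils::read.csv(hist_csv)), nrow(fit$history))
})
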