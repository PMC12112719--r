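#' Sequence encoding specification
#'
#' Fixed-length positional encoding used by the generator: every sequence
#' is padded to \code{max_len} positions, each position a 21-way one-hot
#' over the 20 amino acids plus one padding token.
#'
#' @param max_len Maximum sequence length (default 164); must be at least
#'   the longest training sequence.
#' @return A list of class \code{"encoding_spec"} with \code{max_len},
#'   \code{alphabet} (21 symbols, padding last) and \code{pad} (the pad
#'   index, 21).
#' @export
encoding_spec <- function(max_len = 164L) {
  if (max_len < 1L) abort_input("max_len must be positive")
  structure(list(max_len = as.integer(max_len),
                 alphabet = c(AA_ALPHABET, "-"), pad = 21L),
            class = "encoding_spec")
}

# Integer token row (length max_len, pad-filled) for one sequence.
tokenize <- function(sequence, spec) {
  check_sequence(sequence, allow_empty = TRUE)
  L <- nchar(sequence)
  if (L > spec$max_len)
    abort_input("sequence longer than max_len (", spec$max_len, ")")
  idx <- match(strsplit(sequence, "")[[1]], AA_ALPHABET)
  c(idx, rep(spec$pad, spec$max_len - L))
}

#' One-hot encode a sequence
#'
#' @param sequence Amino-acid string of length at most \code{max_len}
#'   (may be empty, yielding an all-padding matrix).
#' @param spec An \code{\link{encoding_spec}}.
#' @return A \code{max_len} x 21 matrix; rows for residues are unit
#'   vectors on amino-acid columns, trailing rows are unit vectors on the
#'   padding column, and every row sums to 1.
#' @export
one_hot_encode <- function(sequence, spec = encoding_spec()) {
  tok <- tokenize(sequence, spec)
  m <- matrix(0, spec$max_len, 21L,
              dimnames = list(NULL, spec$alphabet))
  m[cbind(seq_len(spec$max_len), tok)] <- 1
  m
}

#' Decode a one-hot (or probability) matrix back to a sequence
#'
#' Takes the argmax symbol per row and truncates at the first padding row.
#' Exact inverse of \code{\link{one_hot_encode}} on valid inputs.
#'
#' @param m A \code{max_len} x 21 matrix.
#' @param spec An \code{\link{encoding_spec}}.
#' @return An amino-acid string.
#' @export
one_hot_decode <- function(m, spec = encoding_spec()) {
  tok <- max.col(m, ties.method = "first")
  stop_at <- which(tok == spec$pad)
  if (length(stop_at)) tok <- tok[seq_len(stop_at[1] - 1L)]
  paste(AA_ALPHABET[tok], collapse = "")
}

#' Generator hyper-parameters
#'
#' Architecture and optimisation settings of the LSTM variational
#' autoencoder: a 256-unit LSTM encoder followed by a 128-unit fully
#' connected layer feeding linear mean/log-variance heads; a decoder whose
#' initial hidden and cell states are produced from the latent vector by
#' two 256-unit linear maps, followed by a 256-unit LSTM emitting 21-way
#' token logits. Trained end to end on the evidence lower bound (ELBO)
#' with Adam and validation-loss early stopping.
#'
#' @param encoder_lstm_units Encoder LSTM width (default 256).
#' @param encoder_fc_units Fully connected layer width (default 128).
#' @param latent_dim Latent dimension (default 128).
#' @param decoder_state_units Width of the two linear maps initialising
#'   the decoder hidden and cell states (default 256; must equal
#'   \code{decoder_lstm_units}).
#' @param decoder_lstm_units Decoder LSTM width (default 256).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param max_epochs Maximum training epochs (default 200).
#' @param early_stop_patience Epochs of non-improving validation loss
#'   tolerated before stopping (default 5).
#' @param validation_fraction Fraction of records held out for validation
#'   (default 0.1).
#' @param batch_size Minibatch size (default 64).
#' @param seed Integer seed controlling the split, initialisation,
#'   shuffling and reparameterisation noise.
#' @return A list of class \code{"vae_config"}.
#' @export
vae_config <- function(encoder_lstm_units = 256L, encoder_fc_units = 128L,
                       latent_dim = 128L, decoder_state_units = 256L,
                       decoder_lstm_units = 256L, learning_rate = 0.001,
                       max_epochs = 200L, early_stop_patience = 5L,
                       validation_fraction = 0.1, batch_size = 64L,
                       seed = 1L) {
  units <- c(encoder_lstm_units, encoder_fc_units, latent_dim,
             decoder_state_units, decoder_lstm_units, batch_size)
  if (any(units < 1L)) abort_input("unit counts must be positive")
  if (decoder_state_units != decoder_lstm_units)
    abort_input("decoder state maps must match the decoder LSTM width")
  if (early_stop_patience < 1L) abort_input("patience must be >= 1")
  if (validation_fraction <= 0 || validation_fraction >= 1)
    abort_input("validation_fraction must be in (0, 1)")
  structure(list(encoder_lstm_units = as.integer(encoder_lstm_units),
                 encoder_fc_units = as.integer(encoder_fc_units),
                 latent_dim = as.integer(latent_dim),
                 decoder_state_units = as.integer(decoder_state_units),
                 decoder_lstm_units = as.integer(decoder_lstm_units),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 validation_fraction = validation_fraction,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "vae_config")
}

#' Generation settings
#'
#' @param n_sequences Number of sequences to generate.
#' @param temperature Softmax temperature for token sampling; higher
#'   values increase diversity, values at or below 1e-6 reduce to greedy
#'   (argmax) decoding. Default 1.
#' @param seed Integer seed for the latent draws and token sampling.
#' @return A list of class \code{"generation_config"}.
#' @export
generation_config <- function(n_sequences, temperature = 1.0, seed = 1L) {
  if (n_sequences < 1L) abort_input("n_sequences must be positive")
  if (temperature <= 0) abort_input("temperature must be positive")
  structure(list(n_sequences = as.integer(n_sequences),
                 temperature = temperature, seed = as.integer(seed)),
            class = "generation_config")
}

## ---- internals: parameter handling -------------------------------------

vae_init_params <- function(cfg) {
  He <- cfg$encoder_lstm_units; Fd <- cfg$encoder_fc_units
  Z <- cfg$latent_dim; Hd <- cfg$decoder_lstm_units
  mat <- function(nr, nc) {
    s <- sqrt(1 / nr)
    matrix(stats::runif(nr * nc, -s, s), nr, nc)
  }
  list(Wx_e = mat(21L, 4L * He), Wh_e = mat(He, 4L * He),
       b_e = numeric(4L * He),
       W_f = mat(He, Fd), b_f = numeric(Fd),
       W_mu = mat(Fd, Z), b_mu = numeric(Z),
       W_lv = mat(Fd, Z), b_lv = numeric(Z),
       W_h0 = mat(Z, Hd), b_h0 = numeric(Hd),
       W_c0 = mat(Z, Hd), b_c0 = numeric(Hd),
       Wx_d = mat(21L, 4L * Hd), Wh_d = mat(Hd, 4L * Hd),
       b_d = numeric(4L * Hd),
       W_o = mat(Hd, 21L), b_o = numeric(21L))
}

sigm <- function(x) 1 / (1 + exp(-x))

# One LSTM step; a = X W_x + H W_h + b with gate blocks (i, f, g, o).
lstm_step <- function(X, h, c, Wx, Wh, b, H) {
  a <- X %*% Wx + h %*% Wh
  a <- sweep(a, 2, b, `+`)
  i <- sigm(a[, seq_len(H), drop = FALSE])
  f <- sigm(a[, H + seq_len(H), drop = FALSE])
  g <- tanh(a[, 2L * H + seq_len(H), drop = FALSE])
  o <- sigm(a[, 3L * H + seq_len(H), drop = FALSE])
  cn <- f * c + i * g
  tc <- tanh(cn)
  hn <- o * tc
  list(h = hn, c = cn, i = i, f = f, g = g, o = o, tc = tc,
       h_prev = h, c_prev = c, X = X)
}

# Backward through one LSTM step. Returns dh_prev, dc_prev and gradient
# contributions; `cache` is the forward step's output list.
lstm_step_back <- function(dh, dc, cache, Wx, Wh) {
  do_ <- dh * cache$tc
  dc <- dc + dh * cache$o * (1 - cache$tc^2)
  di <- dc * cache$g
  dg <- dc * cache$i
  df <- dc * cache$c_prev
  dc_prev <- dc * cache$f
  da <- cbind(di * cache$i * (1 - cache$i),
              df * cache$f * (1 - cache$f),
              dg * (1 - cache$g^2),
              do_ * cache$o * (1 - cache$o))
  list(dWx = crossprod(cache$X, da),
       dWh = crossprod(cache$h_prev, da),
       db = colSums(da),
       dh_prev = tcrossprod(da, Wh) ,
       dc_prev = dc_prev)
}

onehot_rows <- function(tok_col, B) {
  X <- matrix(0, B, 21L)
  X[cbind(seq_len(B), tok_col)] <- 1
  X
}

# Full forward pass on a token matrix (B x T). When `eps` is NULL the
# latent is taken at its mean (used for validation and encoding).
vae_forward <- function(params, tok, cfg, eps = NULL, keep_cache = FALSE) {
  B <- nrow(tok); T <- ncol(tok)
  He <- cfg$encoder_lstm_units; Hd <- cfg$decoder_lstm_units
  h <- matrix(0, B, He); c <- matrix(0, B, He)
  enc_cache <- if (keep_cache) vector("list", T) else NULL
  for (t in seq_len(T)) {
    st <- lstm_step(onehot_rows(tok[, t], B), h, c,
                    params$Wx_e, params$Wh_e, params$b_e, He)
    h <- st$h; c <- st$c
    if (keep_cache) enc_cache[[t]] <- st
  }
  f_pre <- sweep(h %*% params$W_f, 2, params$b_f, `+`)
  f_out <- tanh(f_pre)
  mu <- sweep(f_out %*% params$W_mu, 2, params$b_mu, `+`)
  lv <- sweep(f_out %*% params$W_lv, 2, params$b_lv, `+`)
  z <- if (is.null(eps)) mu else mu + exp(lv / 2) * eps
  h0_pre <- sweep(z %*% params$W_h0, 2, params$b_h0, `+`)
  c0_pre <- sweep(z %*% params$W_c0, 2, params$b_c0, `+`)
  hd <- tanh(h0_pre); cd <- tanh(c0_pre)
  h0_d <- hd; c0_d <- cd
  dec_cache <- if (keep_cache) vector("list", T) else NULL
  probs <- if (keep_cache) vector("list", T) else NULL
  recon <- 0
  for (t in seq_len(T)) {
    Xin <- if (t == 1L) matrix(0, B, 21L) else onehot_rows(tok[, t - 1L], B)
    st <- lstm_step(Xin, hd, cd, params$Wx_d, params$Wh_d, params$b_d, Hd)
    hd <- st$h; cd <- st$c
    logits <- sweep(hd %*% params$W_o, 2, params$b_o, `+`)
    logits <- logits - apply(logits, 1, max)
    p <- exp(logits)
    p <- p / rowSums(p)
    recon <- recon - sum(log(p[cbind(seq_len(B), tok[, t])] + 1e-12))
    if (keep_cache) { dec_cache[[t]] <- st; probs[[t]] <- p }
  }
  recon <- recon / B
  kl <- sum(-0.5 * (1 + lv - mu^2 - exp(lv))) / B
  list(recon = recon, kl = kl, loss = recon + kl,
       mu = mu, lv = lv, z = z, f_out = f_out, h_enc = h,
       h0_d = h0_d, c0_d = c0_d,
       enc_cache = enc_cache, dec_cache = dec_cache, probs = probs,
       eps = eps)
}

# Gradients of the mean-per-sample ELBO loss for one minibatch.
vae_backward <- function(params, tok, cfg, fwd) {
  B <- nrow(tok); T <- ncol(tok)
  He <- cfg$encoder_lstm_units; Hd <- cfg$decoder_lstm_units
  g <- lapply(params, function(p) if (is.matrix(p)) p * 0 else numeric(length(p)))
  dh <- matrix(0, B, Hd); dc <- matrix(0, B, Hd)
  for (t in rev(seq_len(T))) {
    dlog <- (fwd$probs[[t]] - onehot_rows(tok[, t], B)) / B
    cache <- fwd$dec_cache[[t]]
    g$W_o <- g$W_o + crossprod(cache$h, dlog)
    g$b_o <- g$b_o + colSums(dlog)
    dh <- dh + tcrossprod(dlog, params$W_o)
    bk <- lstm_step_back(dh, dc, cache, params$Wx_d, params$Wh_d)
    g$Wx_d <- g$Wx_d + bk$dWx; g$Wh_d <- g$Wh_d + bk$dWh
    g$b_d <- g$b_d + bk$db
    dh <- bk$dh_prev; dc <- bk$dc_prev
  }
  # initial decoder states through their tanh linear maps
  dh0_pre <- dh * (1 - fwd$h0_d^2)
  dc0_pre <- dc * (1 - fwd$c0_d^2)
  g$W_h0 <- crossprod(fwd$z, dh0_pre); g$b_h0 <- colSums(dh0_pre)
  g$W_c0 <- crossprod(fwd$z, dc0_pre); g$b_c0 <- colSums(dc0_pre)
  dz <- tcrossprod(dh0_pre, params$W_h0) +
    tcrossprod(dc0_pre, params$W_c0)
  dmu <- dz + fwd$mu / B
  dlv <- dz * fwd$eps * exp(fwd$lv / 2) / 2 + (exp(fwd$lv) - 1) / (2 * B)
  g$W_mu <- crossprod(fwd$f_out, dmu); g$b_mu <- colSums(dmu)
  g$W_lv <- crossprod(fwd$f_out, dlv); g$b_lv <- colSums(dlv)
  df_out <- tcrossprod(dmu, params$W_mu) + tcrossprod(dlv, params$W_lv)
  df_pre <- df_out * (1 - fwd$f_out^2)
  g$W_f <- crossprod(fwd$enc_cache[[length(fwd$enc_cache)]]$h, df_pre)
  g$b_f <- colSums(df_pre)
  dh <- tcrossprod(df_pre, params$W_f)
  dc <- matrix(0, B, He)
  for (t in rev(seq_len(T))) {
    bk <- lstm_step_back(dh, dc, fwd$enc_cache[[t]],
                         params$Wx_e, params$Wh_e)
    g$Wx_e <- g$Wx_e + bk$dWx; g$Wh_e <- g$Wh_e + bk$dWh
    g$b_e <- g$b_e + bk$db
    dh <- bk$dh_prev; dc <- bk$dc_prev
  }
  g
}

adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## ---- fitting ------------------------------------------------------------

#' Fit the LSTM variational autoencoder to a scaffold library
#'
#' Trains the sequence generator end to end on the evidence lower bound
#' (ELBO): a token-level cross-entropy reconstruction term plus the
#' analytic KL divergence of the diagonal-Gaussian posterior from the
#' standard-normal prior, averaged per sequence. The decoder is trained
#' with teacher forcing. A seeded random split holds out a validation
#' fraction; training stops at \code{max_epochs} or once the validation
#' loss has not improved for \code{early_stop_patience} consecutive
#' epochs, and the parameters from the best validation epoch are retained.
#' With a fixed seed the history and parameters are reproducible exactly.
#'
#' @param records A \code{\link{seq_records}} table or character vector of
#'   sequences (at least 2).
#' @param cfg A \code{\link{vae_config}}.
#' @param spec An \code{\link{encoding_spec}}; its \code{max_len} must
#'   cover the longest training sequence.
#' @param quiet Suppress the per-epoch progress line (default TRUE).
#' @return An object of class \code{"seq_vae"} with elements
#'   \code{params}, \code{config}, \code{spec}, \code{history} (data frame
#'   with per-epoch \code{train_elbo}, \code{val_elbo}, \code{recon},
#'   \code{kl}) and \code{best_epoch}.
#' @seealso \code{\link{vae_generate}}, \code{\link{simulate.seq_vae}},
#'   \code{\link{predict.seq_vae}}
#' @export
vae_fit <- function(records, cfg = vae_config(), spec = encoding_spec(),
                    quiet = TRUE) {
  seqs <- if (is.data.frame(records)) records$sequence else records
  if (length(seqs) < 2L) abort_input("need at least 2 training sequences")
  tok <- t(vapply(seqs, tokenize, integer(spec$max_len), spec = spec))
  dimnames(tok) <- NULL
  n <- nrow(tok)
  with_seed(cfg$seed, {
    n_val <- max(1L, floor(cfg$validation_fraction * n))
    if (n_val >= n) n_val <- n - 1L
    val_idx <- sample.int(n, n_val)
    train_idx <- setdiff(seq_len(n), val_idx)
    params <- vae_init_params(cfg)
    state <- list(m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0))
    history <- data.frame(epoch = integer(0), train_elbo = numeric(0),
                          val_elbo = numeric(0), recon = numeric(0),
                          kl = numeric(0))
    best_val <- Inf; best_params <- params; best_epoch <- 0L
    stall <- 0L; step <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      tr_loss <- tr_recon <- tr_kl <- 0
      for (b in batches) {
        tb <- tok[b, , drop = FALSE]
        eps <- matrix(stats::rnorm(length(b) * cfg$latent_dim),
                      length(b), cfg$latent_dim)
        fwd <- vae_forward(params, tb, cfg, eps = eps, keep_cache = TRUE)
        grads <- vae_backward(params, tb, cfg, fwd)
        step <- step + 1L
        upd <- adam_update(params, grads, state, cfg$learning_rate, step)
        params <- upd$params; state <- upd$state
        w <- length(b) / length(train_idx)
        tr_loss <- tr_loss + fwd$loss * w
        tr_recon <- tr_recon + fwd$recon * w
        tr_kl <- tr_kl + fwd$kl * w
      }
      val <- vae_forward(params, tok[val_idx, , drop = FALSE], cfg,
                         eps = NULL)
      history <- rbind(history, data.frame(
        epoch = epoch, train_elbo = tr_loss, val_elbo = val$loss,
        recon = tr_recon, kl = tr_kl))
      if (!quiet)
        message(sprintf("epoch %3d  train %8.3f  val %8.3f", epoch,
                        tr_loss, val$loss))
      if (val$loss < best_val) {
        best_val <- val$loss; best_params <- params
        best_epoch <- epoch; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$early_stop_patience) break
      }
    }
    structure(list(params = best_params, config = cfg, spec = spec,
                   history = history, best_epoch = best_epoch,
                   n_train = length(train_idx), n_val = n_val),
              class = "seq_vae")
  })
}

## ---- generation ---------------------------------------------------------

# Decode one latent vector autoregressively; returns a string.
decode_one <- function(params, z, spec, Hd, temperature) {
  hd <- tanh(z %*% params$W_h0 + params$b_h0)
  cd <- tanh(z %*% params$W_c0 + params$b_c0)
  Xin <- matrix(0, 1L, 21L)
  out <- integer(0)
  for (t in seq_len(spec$max_len)) {
    st <- lstm_step(Xin, hd, cd, params$Wx_d, params$Wh_d, params$b_d, Hd)
    hd <- st$h; cd <- st$c
    logits <- as.numeric(hd %*% params$W_o + params$b_o)
    if (temperature <= 1e-6) {
      tokn <- which.max(logits)
    } else {
      l <- logits / temperature
      p <- exp(l - max(l)); p <- p / sum(p)
      tokn <- sample.int(21L, 1L, prob = p)
    }
    if (tokn == spec$pad) break
    out <- c(out, tokn)
    Xin <- matrix(0, 1L, 21L); Xin[1L, tokn] <- 1
  }
  paste(AA_ALPHABET[out], collapse = "")
}

#' Decode given latent vectors into sequences
#'
#' Autoregressive temperature-controlled decoding of user-supplied latent
#' vectors. With temperature at or below 1e-6 decoding is greedy
#' (argmax), which is deterministic regardless of seed.
#'
#' @param model A fitted \code{"seq_vae"}.
#' @param z Numeric matrix (n x latent_dim) of latent vectors.
#' @param temperature Softmax temperature (default 1).
#' @param seed Integer seed for token sampling.
#' @return Character vector of decoded sequences.
#' @export
vae_decode <- function(model, z, temperature = 1.0, seed = 1L) {
  z <- matrix(as.numeric(z), ncol = model$config$latent_dim)
  with_seed(seed, {
    vapply(seq_len(nrow(z)), function(i)
      decode_one(model$params, z[i, , drop = FALSE], model$spec,
                 model$config$decoder_lstm_units, temperature), "")
  })
}

#' Generate de novo sequences from the fitted generator
#'
#' Draws latent vectors from the standard-normal prior and decodes them
#' autoregressively with temperature-controlled token sampling; decoding
#' stops at the first padding token, so no padding symbol ever appears
#' inside a returned sequence. Identical seeds give identical output.
#'
#' @param model A fitted \code{"seq_vae"}.
#' @param gen_cfg A \code{\link{generation_config}}.
#' @return Character vector of \code{n_sequences} sequences over the
#'   20-letter alphabet.
#' @export
vae_generate <- function(model, gen_cfg) {
  if (!inherits(model, "seq_vae")) abort_input("model is not a fitted seq_vae")
  with_seed(gen_cfg$seed, {
    Z <- model$config$latent_dim
    vapply(seq_len(gen_cfg$n_sequences), function(i) {
      z <- matrix(stats::rnorm(Z), 1L, Z)
      decode_one(model$params, z, model$spec,
                 model$config$decoder_lstm_units, gen_cfg$temperature)
    }, "")
  })
}

## ---- methods ------------------------------------------------------------

#' @export
print.seq_vae <- function(x, ...) {
  cat("LSTM variational autoencoder for scaffold sequences\n")
  cat(sprintf("  encoder LSTM %d -> FC %d -> latent %d -> decoder LSTM %d\n",
              x$config$encoder_lstm_units, x$config$encoder_fc_units,
              x$config$latent_dim, x$config$decoder_lstm_units))
  cat(sprintf("  trained %d epochs (best validation at epoch %d)\n",
              nrow(x$history), x$best_epoch))
  cat(sprintf("  final ELBO: train %.3f, validation %.3f\n",
              x$history$train_elbo[nrow(x$history)],
              x$history$val_elbo[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.seq_vae <- function(object, ...) {
  h <- object$history
  out <- list(epochs = nrow(h), best_epoch = object$best_epoch,
              n_train = object$n_train, n_val = object$n_val,
              first_recon = h$recon[1], final_recon = h$recon[nrow(h)],
              final_kl = h$kl[nrow(h)],
              best_val_elbo = min(h$val_elbo),
              n_parameters = sum(vapply(object$params, length, 0L)))
  class(out) <- "summary.seq_vae"
  out
}

#' @export
print.summary.seq_vae <- function(x, ...) {
  cat("seq_vae fit summary\n")
  cat(sprintf("  epochs run          %d (best at %d)\n", x$epochs, x$best_epoch))
  cat(sprintf("  records             %d train / %d validation\n",
              x$n_train, x$n_val))
  cat(sprintf("  parameters          %d\n", x$n_parameters))
  cat(sprintf("  reconstruction loss %.3f (epoch 1) -> %.3f (final)\n",
              x$first_recon, x$final_recon))
  cat(sprintf("  final KL term       %.3f\n", x$final_kl))
  cat(sprintf("  best validation ELBO %.3f\n", x$best_val_elbo))
  invisible(x)
}

#' @export
coef.seq_vae <- function(object, ...) object$params

#' Plot the training history of a fitted generator
#'
#' Draws the per-epoch training and validation ELBO curves.
#'
#' @param x A fitted \code{"seq_vae"}.
#' @param ... Passed to \code{matplot}.
#' @return Invisibly, the history data frame.
#' @export
plot.seq_vae <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_elbo, h$val_elbo), type = "l",
                    lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "ELBO loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  invisible(h)
}

#' Encode sequences with a fitted generator
#'
#' Maps sequences to their posterior latent statistics or, with
#' \code{type = "reconstruction"}, to the greedy reconstruction decoded
#' from the latent mean.
#'
#' @param object A fitted \code{"seq_vae"}.
#' @param newdata Character vector of sequences (or a
#'   \code{\link{seq_records}} table).
#' @param type \code{"latent"} (default: list with \code{mu},
#'   \code{logvar} matrices) or \code{"reconstruction"} (character
#'   vector).
#' @param ... Unused.
#' @return See \code{type}.
#' @export
predict.seq_vae <- function(object, newdata,
                            type = c("latent", "reconstruction"), ...) {
  type <- match.arg(type)
  seqs <- if (is.data.frame(newdata)) newdata$sequence else newdata
  tok <- t(vapply(seqs, tokenize, integer(object$spec$max_len),
                  spec = object$spec))
  dimnames(tok) <- NULL
  fwd <- vae_forward(object$params, tok, object$config, eps = NULL)
  if (type == "latent") return(list(mu = fwd$mu, logvar = fwd$lv))
  vae_decode(object, fwd$mu, temperature = 1e-7)
}

#' Simulate (generate) sequences from a fitted generator
#'
#' \code{simulate} interface to \code{\link{vae_generate}}: draws
#' \code{nsim} standard-normal latent vectors and decodes them.
#'
#' @param object A fitted \code{"seq_vae"}.
#' @param nsim Number of sequences (default 1).
#' @param seed Integer seed (default 1).
#' @param temperature Sampling temperature (default 1).
#' @param ... Unused.
#' @return Character vector of length \code{nsim}.
#' @export
simulate.seq_vae <- function(object, nsim = 1L, seed = 1L,
                             temperature = 1.0, ...) {
  vae_generate(object, generation_config(nsim, temperature, seed))
}

#' Save / load a fitted generator
#'
#' The checkpoint is a single serialised archive holding parameters,
#' configuration, encoding spec and training history; loading restores the
#' model bit-identically, so generation after a save/load round trip
#' matches generation before it for the same seed.
#'
#' @param model A fitted \code{"seq_vae"}.
#' @param path Checkpoint path.
#' @return \code{vae_save}: invisibly, \code{path}; \code{vae_load}: the
#'   restored \code{"seq_vae"}.
#' @export
vae_save <- function(model, path) {
  saveRDS(model, path, version = 2)
  invisible(path)
}

#' @rdname vae_save
#' @export
vae_load <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "seq_vae")) abort_input("not a seq_vae checkpoint")
  model
}

#' Write the training history as CSV
#'
#' Columns: epoch, train_elbo, val_elbo, recon, kl.
#'
#' @param model A fitted \code{"seq_vae"}.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_history_csv <- function(model, path) {
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
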