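# Internal helpers shared across modules.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @keywords internal
#' @noRd
abort_input <- function(...) stop(..., call. = FALSE)

#' Check that a string is a valid amino-acid sequence
#' @keywords internal
#' @noRd
check_sequence <- function(x, what = "sequence", allow_empty = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    abort_input(what, " must be a single string")
  if (!allow_empty && nchar(x) == 0L)
    abort_input(what, " must be non-empty")
  bad <- setdiff(unique(strsplit(x, "")[[1]]), AA_ALPHABET)
  if (length(bad))
    abort_input(what, " contains invalid letters: ", paste(bad, collapse = ", "))
  invisible(x)
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so library code never clobbers the user's stream.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Stable derivation of per-stage seeds from one master seed; keeps every
# derived value inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
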