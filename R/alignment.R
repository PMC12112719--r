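#' Global-alignment scoring parameters
#'
#' Scoring used for every pairwise sequence alignment in the package:
#' BLOSUM62 substitution scores with affine gap penalties (opening -10,
#' extension -0.5) and a cap on the longest contiguous gap a valid
#' alignment may contain.
#'
#' @param substitution_matrix Name of the substitution matrix shipped with
#'   Biostrings (default \code{"BLOSUM62"}).
#' @param gap_open Gap opening penalty, non-positive (default -10).
#' @param gap_extend Gap extension penalty, non-positive (default -0.5).
#' @param max_gap Longest contiguous gap allowed in the optimal alignment;
#'   alignments exceeding it raise an error rather than silently degrading.
#' @return A list of class \code{"alignment_params"}.
#' @export
alignment_params <- function(substitution_matrix = "BLOSUM62",
                             gap_open = -10, gap_extend = -0.5,
                             max_gap = 50L) {
  if (gap_open > 0 || gap_extend > 0)
    abort_input("gap penalties must be <= 0")
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 max_gap = as.integer(max_gap)),
            class = "alignment_params")
}

.sub_matrix_cache <- new.env(parent = emptyenv())

# Substitution matrices ship as data objects in Biostrings; load lazily
# and cache.
get_sub_matrix <- function(name) {
  if (is.null(.sub_matrix_cache[[name]])) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    .sub_matrix_cache[[name]] <- get(name, envir = e)
  }
  .sub_matrix_cache[[name]]
}

# Needleman-Wunsch global alignment via Biostrings; returns the two aligned
# strings (with "-" gaps) of equal length, end gaps included.
align_pair <- function(a, b, params = alignment_params()) {
  check_sequence(a, "sequence a")
  check_sequence(b, "sequence b")
  mat <- get_sub_matrix(params$substitution_matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat,
    gapOpening = -params$gap_open, gapExtension = -params$gap_extend,
    type = "global")
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  max_run <- function(x) {
    r <- rle(strsplit(x, "")[[1]] == "-")
    if (any(r$values)) max(r$lengths[r$values]) else 0L
  }
  if (max(max_run(p), max_run(s)) > params$max_gap)
    abort_input("alignment contains a gap longer than max_gap (",
                params$max_gap, ")")
  list(a = p, b = s)
}

#' Pairwise sequence identity under global alignment
#'
#' Globally aligns the two sequences (BLOSUM62, affine gaps; see
#' \code{\link{alignment_params}}) and returns the fraction of identical
#' aligned columns over the total alignment length, gap columns included in
#' the denominator. The measure is symmetric and equals 1 exactly when the
#' sequences are equal.
#'
#' @param a,b Amino-acid sequences (non-empty strings).
#' @param params \code{\link{alignment_params}}.
#' @return Identity fraction in [0, 1].
#' @examples
#' pairwise_identity(ubiquitin_wt(), ubiquitin_wt())
#' @export
pairwise_identity <- function(a, b, params = alignment_params()) {
  if (identical(a, b)) {
    check_sequence(a)
    return(1.0)
  }
  al <- align_pair(a, b, params)
  pa <- strsplit(al$a, "")[[1]]
  pb <- strsplit(al$b, "")[[1]]
  sum(pa == pb & pa != "-") / length(pa)
}
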