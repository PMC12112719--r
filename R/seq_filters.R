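#' Post-generation filter configuration
#'
#' Window filters applied to generated scaffold sequences before structure
#' modelling: sequence identity to wild-type ubiquitin between 75 and 90
#' percent (inclusive), length between 72 and 84 residues (inclusive), and
#' a per-residue model-confidence floor of pLDDT 50.
#'
#' @param identity_min,identity_max Inclusive identity window to the
#'   reference, fractions with \code{0 <= identity_min < identity_max <= 1}.
#' @param length_min,length_max Inclusive residue-count window.
#' @param plddt_floor Minimum per-residue pLDDT; a model with any residue
#'   below this is discarded.
#' @param reference Reference sequence (default wild-type ubiquitin).
#' @return A list of class \code{"filter_config"}.
#' @export
filter_config <- function(identity_min = 0.75, identity_max = 0.90,
                          length_min = 72L, length_max = 84L,
                          plddt_floor = 50, reference = ubiquitin_wt()) {
  if (!(identity_min >= 0 && identity_min < identity_max && identity_max <= 1))
    abort_input("need 0 <= identity_min < identity_max <= 1")
  if (length_min > length_max) abort_input("length_min must be <= length_max")
  structure(list(identity_min = identity_min, identity_max = identity_max,
                 length_min = as.integer(length_min),
                 length_max = as.integer(length_max),
                 plddt_floor = plddt_floor, reference = reference),
            class = "filter_config")
}

#' Filter generated sequences by length and identity to the reference
#'
#' Keeps a sequence iff its length lies in the configured window and its
#' alignment-based identity to the reference lies in the identity window,
#' all bounds inclusive. Input order is preserved.
#'
#' @param sequences Character vector of candidate sequences.
#' @param cfg A \code{\link{filter_config}}.
#' @param params \code{\link{alignment_params}} for the identity
#'   computation.
#' @return A list with \code{kept} (character vector) and \code{report}
#'   (data frame with per-sequence \code{id}, \code{length},
#'   \code{identity}, \code{kept}).
#' @export
filter_generated <- function(sequences, cfg = filter_config(),
                             params = alignment_params()) {
  n <- length(sequences)
  ids <- names(sequences) %||% sprintf("seq_%d", seq_len(n))
  len <- nchar(sequences)
  # sequences so divergent that the alignment needs a gap beyond max_gap
  # cannot be inside the identity window; they report NA and are rejected
  ident <- vapply(sequences, function(s)
    tryCatch(pairwise_identity(s, cfg$reference, params),
             error = function(e) NA_real_), 0, USE.NAMES = FALSE)
  kept <- !is.na(ident) &
    len >= cfg$length_min & len <= cfg$length_max &
    ident >= cfg$identity_min & ident <= cfg$identity_max
  report <- data.frame(id = ids, length = len, identity = ident,
                       kept = kept, stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(kept = unname(sequences[kept]), report = report)
}

#' Filter predicted models by per-residue confidence
#'
#' Discards every model whose confidence track dips below the floor at any
#' residue; this is the strictest reading of rejecting models with
#' low-confidence regions. Also reports the mean over models of the
#' per-model mean pLDDT, summarising overall model quality of the input
#' set.
#'
#' @param models A list of model-quality entries, each a list with
#'   \code{id} and \code{plddt} (numeric vector in [0, 100], one value per
#'   residue).
#' @param floor Minimum tolerated per-residue pLDDT (default 50).
#' @return A list with \code{kept} (the surviving entries),
#'   \code{mean_plddt} (scalar, over the full input set) and \code{report}
#'   (data frame: \code{id}, \code{min_plddt}, \code{mean_plddt},
#'   \code{kept}).
#' @export
plddt_filter <- function(models, floor = 50) {
  if (length(models) == 0L) abort_input("no models supplied")
  for (m in models) {
    if (length(m$plddt) == 0L || anyNA(m$plddt))
      abort_input("model ", m$id %||% "?", " has an empty or invalid pLDDT track")
  }
  mins <- vapply(models, function(m) min(m$plddt), 0)
  means <- vapply(models, function(m) mean(m$plddt), 0)
  keep <- mins >= floor
  report <- data.frame(
    id = vapply(models, function(m) as.character(m$id %||% NA), ""),
    min_plddt = mins, mean_plddt = means, kept = keep,
    stringsAsFactors = FALSE)
  list(kept = models[keep], mean_plddt = mean(means), report = report)
}

#' Read a per-residue pLDDT track from CSV
#'
#' Expects columns \code{residue_index} and \code{plddt}; rows are sorted
#' by residue index.
#'
#' @param path CSV path.
#' @param id Identifier to attach (default: file name without extension).
#' @return A model-quality entry usable with \code{\link{plddt_filter}}.
#' @export
read_plddt_csv <- function(path, id = sub("\\.[^.]*$", "", basename(path))) {
  df <- utils::read.csv(path)
  if (!all(c("residue_index", "plddt") %in% names(df)))
    abort_input("pLDDT CSV needs columns residue_index, plddt")
  df <- df[order(df$residue_index), ]
  list(id = id, plddt = df$plddt)
}

#' Extract a pLDDT track from the B-factor column of a PDB model
#'
#' Predicted-structure files conventionally store per-residue confidence in
#' the B-factor field; the track is read off the Calpha atoms in residue
#' order.
#'
#' @param path PDB path.
#' @param id Identifier to attach.
#' @return A model-quality entry usable with \code{\link{plddt_filter}}.
#' @export
read_plddt_pdb <- function(path, id = sub("\\.[^.]*$", "", basename(path))) {
  s <- read_ca_structure(path)
  if (all(is.na(s$plddt))) abort_input("PDB has no B-factor confidence track")
  list(id = id, plddt = s$plddt)
}

#' Write a sequence-filter report as TSV
#'
#' @param report Data frame from \code{\link{filter_generated}} or
#'   \code{\link{plddt_filter}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
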