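#' The wild-type human ubiquitin sequence
#'
#' Returns the 76-residue wild-type human ubiquitin sequence (UniProt
#' P0CG48, residues 1-76), the scaffold reference against which designed
#' binder candidates are compared for sequence identity.
#'
#' @return A single character string of length 76.
#' @examples
#' nchar(ubiquitin_wt())
#' @export
ubiquitin_wt <- function() {
  "MQIFVKTLTGKTITLEVEPSDTIENVKAKIQDKEGIPPDQQRLIFAGKQLEDGRTLSDYNIQKESTLHLVLRLRGG"
}

#' Dataset-curation configuration
#'
#' Parameters controlling library curation: the identity threshold used when
#' deduplicating monomers, and the N-terminal 3-mer motifs that mark the
#' start of each scaffold unit in head-to-tail dimeric constructs.
#'
#' @param dedup_identity Pairwise identity at or above which a later record
#'   is treated as a duplicate of an earlier one. Fraction in (0, 1];
#'   default 0.99.
#' @param split_motifs Character vector of length-3 N-terminal motifs used
#'   to locate the junction of dimeric constructs.
#' @param ubiquitin_wt The scaffold reference sequence (76 residues).
#' @return A list of class \code{"dataset_config"}.
#' @export
dataset_config <- function(dedup_identity = 0.99,
                           split_motifs = c("MQI", "MRI", "MAS", "MTI"),
                           ubiquitin_wt = ubinder::ubiquitin_wt()) {
  if (!is.numeric(dedup_identity) || dedup_identity <= 0 || dedup_identity > 1)
    abort_input("dedup_identity must be in (0, 1]")
  if (any(nchar(split_motifs) != 3L))
    abort_input("split motifs must be 3-mers")
  if (nchar(ubiquitin_wt) != 76L)
    abort_input("ubiquitin_wt must have 76 residues")
  structure(list(dedup_identity = dedup_identity,
                 split_motifs = toupper(split_motifs),
                 ubiquitin_wt = ubiquitin_wt),
            class = "dataset_config")
}

#' Construct a table of scaffold sequence records
#'
#' The library container used throughout curation: a data frame with one row
#' per scaffold variant, carrying the sequence and optional affinity
#' annotations.
#'
#' @param id Character vector of identifiers.
#' @param sequence Character vector of amino-acid sequences (uppercase,
#'   20-letter alphabet).
#' @param kd_nM Optional numeric vector of equilibrium dissociation
#'   constants in nM (positive where present).
#' @param target Optional character vector of target labels.
#' @param binder_class Optional character vector over
#'   \code{c("SB","MB","WB","NB")}.
#' @return A data frame of class \code{"seq_records"} with columns
#'   \code{id}, \code{sequence}, \code{kd_nM}, \code{target}, \code{class}.
#' @export
seq_records <- function(id, sequence, kd_nM = NA_real_, target = NA_character_,
                        binder_class = NA_character_) {
  n <- length(sequence)
  stopifnot(length(id) == n)
  for (s in sequence) check_sequence(s)
  kd_nM <- rep_len(as.numeric(kd_nM), n)
  if (any(!is.na(kd_nM) & kd_nM <= 0))
    abort_input("kd_nM must be positive where present")
  binder_class <- rep_len(as.character(binder_class), n)
  bad <- !is.na(binder_class) & !binder_class %in% c("SB", "MB", "WB", "NB")
  if (any(bad)) abort_input("invalid binder class: ", binder_class[bad][1])
  out <- data.frame(id = as.character(id), sequence = sequence,
                    kd_nM = kd_nM, target = rep_len(as.character(target), n),
                    class = binder_class, stringsAsFactors = FALSE)
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Classify a binder by its dissociation constant
#'
#' Binders are banded by K_D: strong binders (SB) below 10 nM, medium
#' binders (MB) from 10 nM up to (but excluding) 100 nM, and weak binders
#' (WB) at 100 nM or above. The non-binder class NB is reserved for
#' explicit "no binding detected" annotations and is never produced from a
#' numeric K_D.
#'
#' @param kd_nM Numeric vector of positive dissociation constants (nM).
#' @return Character vector over \code{c("SB","MB","WB")}.
#' @examples
#' classify_binder(c(5.4, 29.8, 100))
#' @export
classify_binder <- function(kd_nM) {
  if (length(kd_nM) == 0L || !is.numeric(kd_nM) || anyNA(kd_nM) || any(kd_nM <= 0))
    abort_input("kd_nM must be positive and non-missing")
  ifelse(kd_nM < 10, "SB", ifelse(kd_nM < 100, "MB", "WB"))
}

# Leftmost strictly-internal occurrence of any motif, or NA.
internal_motif_pos <- function(sequence, motifs) {
  hits <- unlist(lapply(motifs, function(m) {
    p <- gregexpr(m, sequence, fixed = TRUE)[[1]]
    p[p > 1]
  }))
  if (length(hits) == 0L) NA_integer_ else min(hits)
}

#' Split a dimeric scaffold construct into two monomers
#'
#' Head-to-tail dimeric constructs concatenate two scaffold units, each
#' beginning with one of the N-terminal motifs. The record is cut at the
#' leftmost motif occurrence strictly after position 1; further occurrences
#' are ignored, so a dimer yields exactly two monomers. Records with no
#' internal motif are returned unchanged.
#'
#' @param record A one-row \code{\link{seq_records}} table (or a list with
#'   \code{id} and \code{sequence}).
#' @param cfg A \code{\link{dataset_config}}.
#' @return A \code{seq_records} table with one (monomer) or two (split
#'   dimer) rows; annotations are copied to both halves. The concatenation
#'   of the output sequences always equals the input sequence.
#' @export
split_dimer <- function(record, cfg = dataset_config()) {
  seqs <- record$sequence
  if (length(seqs) != 1L) abort_input("split_dimer expects a single record")
  check_sequence(seqs)
  pos <- internal_motif_pos(seqs, cfg$split_motifs)
  if (is.na(pos)) {
    return(seq_records(record$id, seqs, record$kd_nM %||% NA,
                       record$target %||% NA, record$class %||% NA))
  }
  halves <- c(substr(seqs, 1L, pos - 1L), substr(seqs, pos, nchar(seqs)))
  seq_records(paste0(record$id, c("_m1", "_m2")), halves,
              rep((record$kd_nM %||% NA)[1], 2),
              rep((record$target %||% NA)[1], 2),
              rep((record$class %||% NA)[1], 2))
}

#' Split every dimeric record in a library
#'
#' @param records A \code{\link{seq_records}} table.
#' @param cfg A \code{\link{dataset_config}}.
#' @return A \code{seq_records} table where every dimer has been replaced by
#'   its two monomer halves, in input order.
#' @export
split_dimers <- function(records, cfg = dataset_config()) {
  parts <- lapply(seq_len(nrow(records)), function(i) split_dimer(records[i, ], cfg))
  out <- do.call(rbind, parts)
  class(out) <- c("seq_records", "data.frame")
  rownames(out) <- NULL
  out
}

#' Deduplicate a sequence library at an identity threshold
#'
#' Greedy single-pass deduplication: records are scanned in input order and
#' a record is dropped iff its pairwise identity (alignment-based, see
#' \code{\link{pairwise_identity}}) to an already-kept record is at or above
#' \code{cfg$dedup_identity}. The first occurrence wins and output order
#' preserves input order.
#'
#' @param records A \code{\link{seq_records}} table.
#' @param cfg A \code{\link{dataset_config}}.
#' @param params \code{\link{alignment_params}} used for the identity
#'   computation.
#' @return The kept subset, same class and column layout.
#' @export
deduplicate <- function(records, cfg = dataset_config(),
                        params = alignment_params()) {
  n <- nrow(records)
  if (n == 0L) return(records)
  thr <- cfg$dedup_identity
  keep <- logical(n)
  kept_seqs <- character(0)
  kept_chars <- list()
  kept_len <- integer(0)
  for (i in seq_len(n)) {
    s <- records$sequence[i]
    sc <- strsplit(s, "")[[1]]
    ls <- length(sc)
    dup <- FALSE
    for (j in seq_along(kept_seqs)) {
      lk <- kept_len[j]
      # identity never exceeds min(len)/max(len): prune without aligning
      if (min(ls, lk) / max(ls, lk) < thr) next
      if (s == kept_seqs[j]) { dup <- TRUE; break }
      if (ls == lk) {
        # at high thresholds a gapped alignment of equal-length sequences
        # cannot reach the threshold, so ungapped identity decides
        u <- sum(sc == kept_chars[[j]]) / ls
        if (u >= thr) { dup <- TRUE; break }
        if ((ls - 1) / (ls + 2) < thr) next
      }
      if (pairwise_identity(s, kept_seqs[j], params) >= thr) {
        dup <- TRUE; break
      }
    }
    if (!dup) {
      keep[i] <- TRUE
      kept_seqs <- c(kept_seqs, s)
      kept_chars <- c(kept_chars, list(sc))
      kept_len <- c(kept_len, ls)
    }
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a scaffold library from FASTA
#'
#' Description lines may carry optional \code{key=value} tokens
#' (\code{kd_nM=5.4 target=HER3 class=SB}) after the identifier; these are
#' parsed into the record columns.
#'
#' @param path Path to a FASTA file.
#' @return A \code{\link{seq_records}} table.
#' @export
read_seq_library <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  toks <- strsplit(headers, "\\s+")
  ids <- vapply(toks, `[`, "", 1L)
  get_tok <- function(t, key) {
    hit <- grep(paste0("^", key, "="), t, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA_character_
  }
  kd <- as.numeric(vapply(toks, get_tok, "", "kd_nM"))
  tg <- vapply(toks, get_tok, "", "target")
  cl <- vapply(toks, get_tok, "", "class")
  seq_records(ids, as.character(aa), kd, tg, cl)
}

#' Write a scaffold library to FASTA
#'
#' Sequences are wrapped at 60 columns; non-missing annotations are emitted
#' as \code{key=value} tokens on the description line.
#'
#' @param records A \code{\link{seq_records}} table.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_seq_library <- function(records, path) {
  desc <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    toks <- r$id
    if (!is.na(r$kd_nM)) toks <- c(toks, sprintf("kd_nM=%g", r$kd_nM))
    if (!is.na(r$target)) toks <- c(toks, paste0("target=", r$target))
    if (!is.na(r$class)) toks <- c(toks, paste0("class=", r$class))
    paste(toks, collapse = " ")
  }, "")
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- desc
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}
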