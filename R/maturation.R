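#' Maturation configuration
#'
#' Defaults for the affinity-maturation bookkeeping stage: the identity
#' threshold at which a candidate sequence pool is clustered, the number
#' of generated variants per parental hit, and the largest consensus
#' mutant (number of combined substitutions) constructed.
#'
#' @param cluster_identity Identity at or above which a pool member joins
#'   an existing cluster (default 0.975).
#' @param n_generated_per_hit Variants generated per parental hit
#'   (default 100); informational for pool construction.
#' @param max_consensus_order Largest number of single substitutions
#'   combined into one consensus mutant (default 3).
#' @return A list of class \code{"maturation_config"}.
#' @export
maturation_config <- function(cluster_identity = 0.975,
                              n_generated_per_hit = 100L,
                              max_consensus_order = 3L) {
  if (cluster_identity <= 0 || cluster_identity > 1)
    abort_input("cluster_identity must be in (0, 1]")
  if (max_consensus_order < 2L)
    abort_input("max_consensus_order must be >= 2")
  structure(list(cluster_identity = cluster_identity,
                 n_generated_per_hit = as.integer(n_generated_per_hit),
                 max_consensus_order = as.integer(max_consensus_order)),
            class = "maturation_config")
}

#' Greedy centroid clustering of a candidate sequence pool
#'
#' Processes sequences in input order: each sequence joins the first
#' existing cluster whose centroid it matches at or above the identity
#' threshold, otherwise it founds a new cluster and becomes its centroid
#' (the cluster representative). Deterministic and order dependent by
#' design.
#'
#' @param sequences Character vector (optionally named) of pool members.
#' @param cfg A \code{\link{maturation_config}}.
#' @param params \code{\link{alignment_params}} for the identity
#'   computation.
#' @return A list with \code{centroids} (character vector),
#'   \code{assignment} (integer cluster index per input sequence) and
#'   \code{clusters} (list of member index vectors).
#' @export
cluster_pool <- function(sequences, cfg = maturation_config(),
                         params = alignment_params()) {
  n <- length(sequences)
  if (n == 0L) abort_input("empty sequence pool")
  centroids <- character(0)
  assignment <- integer(n)
  for (i in seq_len(n)) {
    s <- sequences[[i]]
    hit <- 0L
    for (j in seq_along(centroids)) {
      ident <- if (s == centroids[j]) 1.0
               else pairwise_identity(s, centroids[j], params)
      if (ident >= cfg$cluster_identity) { hit <- j; break }
    }
    if (hit == 0L) {
      centroids <- c(centroids, s)
      hit <- length(centroids)
    }
    assignment[i] <- hit
  }
  list(centroids = centroids, assignment = assignment,
       clusters = split(seq_len(n), assignment))
}

#' Construct a mutant specification
#'
#' A set of point substitutions relative to a parent sequence, each given
#' as (1-based position, parent residue, replacement residue).
#'
#' @param parent_id Identifier of the parent sequence.
#' @param position Integer vector of 1-based positions (unique).
#' @param from,to Character vectors of single residues; \code{from} must
#'   match the parent at each position when applied.
#' @return A list of class \code{"mutant_spec"}.
#' @export
mutant_spec <- function(parent_id, position = integer(0),
                        from = character(0), to = character(0)) {
  stopifnot(length(position) == length(from), length(from) == length(to))
  if (anyDuplicated(position))
    abort_input("positions must be unique within one mutant spec")
  structure(list(parent_id = as.character(parent_id),
                 position = as.integer(position),
                 from = as.character(from), to = as.character(to)),
            class = "mutant_spec")
}

#' Format a mutant spec as a mutation string
#'
#' @param spec A \code{\link{mutant_spec}}.
#' @return A string such as \code{"K6R+E7Q"} (empty spec formats as
#'   \code{"WT"}).
#' @export
format_mutations <- function(spec) {
  if (length(spec$position) == 0L) return("WT")
  paste(sprintf("%s%d%s", spec$from, spec$position, spec$to), collapse = "+")
}

#' Parse a mutation string into a mutant spec
#'
#' @param x A string such as \code{"K6R"} or \code{"K6R+E7Q"}; \code{"WT"}
#'   parses to an empty spec.
#' @param parent_id Identifier of the parent sequence.
#' @return A \code{\link{mutant_spec}}.
#' @export
parse_mutations <- function(x, parent_id = "parent") {
  if (identical(toupper(x), "WT"))
    return(mutant_spec(parent_id))
  toks <- strsplit(x, "+", fixed = TRUE)[[1]]
  m <- regmatches(toks, regexec("^([A-Z])([0-9]+)([A-Z])$", toks))
  if (any(vapply(m, length, 0L) != 4L))
    abort_input("malformed mutation string: ", x)
  mutant_spec(parent_id,
              position = as.integer(vapply(m, `[`, "", 3L)),
              from = vapply(m, `[`, "", 2L),
              to = vapply(m, `[`, "", 4L))
}

#' Diff a fixed-length variant against its parent
#'
#' Lists every position at which the variant differs from the parent.
#' Variants carrying insertions or deletions are rejected: maturation
#' operates on fixed-length scaffolds.
#'
#' @param parent,variant Amino-acid sequences of equal length.
#' @param parent_id Identifier for the returned spec.
#' @return A \code{\link{mutant_spec}} (empty when the sequences are
#'   identical).
#' @export
diff_mutations <- function(parent, variant, parent_id = "parent") {
  check_sequence(parent, "parent")
  check_sequence(variant, "variant")
  if (nchar(parent) != nchar(variant))
    abort_input("variant length differs from parent; indel-bearing variants are unsupported")
  p <- strsplit(parent, "")[[1]]
  v <- strsplit(variant, "")[[1]]
  idx <- which(p != v)
  mutant_spec(parent_id, idx, p[idx], v[idx])
}

#' Decompose multi-mutants into deduplicated single mutants
#'
#' Takes the union of individual substitutions across a list of
#' (multi-)mutant specs and emits each as a one-substitution spec.
#' Duplicates are merged and the output is ordered by position, then by
#' replacement residue.
#'
#' @param specs List of \code{\link{mutant_spec}} objects sharing one
#'   parent.
#' @return List of single-substitution \code{mutant_spec} objects.
#' @export
enumerate_singles <- function(specs) {
  if (length(specs) == 0L) return(list())
  parent_id <- specs[[1]]$parent_id
  df <- do.call(rbind, lapply(specs, function(s)
    data.frame(position = s$position, from = s$from, to = s$to,
               stringsAsFactors = FALSE)))
  if (is.null(df) || nrow(df) == 0L) return(list())
  df <- unique(df)
  conflict <- stats::aggregate(from ~ position, df,
                               function(x) length(unique(x)))
  if (any(conflict$from > 1L))
    abort_input("inconsistent parent residue across specs at position ",
                conflict$position[conflict$from > 1L][1])
  df <- df[order(df$position, df$to), ]
  lapply(seq_len(nrow(df)), function(i)
    mutant_spec(parent_id, df$position[i], df$from[i], df$to[i]))
}

#' Build consensus double/triple mutants from scored singles
#'
#' Combines the most improving single substitutions into higher-order
#' "consensus" mutants: only singles with strictly negative predicted
#' \eqn{\Delta\Delta G} are combinable, singles touching the same position
#' are never combined, and all position-compatible combinations of order 2
#' up to \code{max_consensus_order} are emitted, built from the improvers
#' ranked most improving first.
#'
#' @param singles List of single-substitution \code{\link{mutant_spec}}
#'   objects.
#' @param ddg Numeric vector of predicted \eqn{\Delta\Delta G} values
#'   (kcal/mol), parallel to \code{singles}.
#' @param cfg A \code{\link{maturation_config}}.
#' @return List of consensus \code{mutant_spec} objects (possibly empty),
#'   ordered by increasing order then by the rank of their components.
#' @export
consensus_mutants <- function(singles, ddg, cfg = maturation_config()) {
  if (length(singles) < 2L) abort_input("need at least 2 scored singles")
  if (length(ddg) != length(singles))
    abort_input("one ddG per single required")
  improving <- which(ddg < 0)
  if (length(improving) == 0L) return(list())
  improving <- improving[order(ddg[improving])]
  parent_id <- singles[[1]]$parent_id
  out <- list()
  for (ord in 2:cfg$max_consensus_order) {
    if (length(improving) < ord) break
    combos <- utils::combn(improving, ord, simplify = FALSE)
    for (cb in combos) {
      pos <- vapply(singles[cb], `[[`, 0L, "position")
      if (anyDuplicated(pos)) next
      o <- order(pos)
      out[[length(out) + 1L]] <- mutant_spec(
        parent_id,
        pos[o],
        vapply(singles[cb], function(s) s$from, "")[o],
        vapply(singles[cb], function(s) s$to, "")[o])
    }
  }
  out
}

#' Apply a mutant specification to a parent sequence
#'
#' @param parent Parent amino-acid sequence.
#' @param spec A \code{\link{mutant_spec}}; every \code{from} residue must
#'   match the parent at its position.
#' @return The mutated sequence (same length as the parent).
#' @export
apply_mutant <- function(parent, spec) {
  check_sequence(parent, "parent")
  chars <- strsplit(parent, "")[[1]]
  if (length(spec$position) == 0L) return(parent)
  if (any(spec$position < 1L | spec$position > length(chars)))
    abort_input("mutation position outside the parent sequence")
  mismatch <- chars[spec$position] != spec$from
  if (any(mismatch))
    abort_input("parent residue mismatch at position ",
                spec$position[mismatch][1], ": expected ",
                spec$from[mismatch][1], ", found ",
                chars[spec$position[mismatch][1]])
  chars[spec$position] <- spec$to
  paste(chars, collapse = "")
}

#' Read scored single mutants from TSV
#'
#' Expects columns \code{mutation} (strings such as \code{K6R}) and
#' \code{ddG}.
#'
#' @param path TSV path.
#' @param parent_id Identifier of the parent sequence.
#' @return A list with \code{singles} (list of \code{\link{mutant_spec}})
#'   and \code{ddg} (numeric).
#' @export
read_scored_singles <- function(path, parent_id = "parent") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("mutation", "ddG") %in% names(df)))
    abort_input("scored singles TSV needs columns mutation, ddG")
  list(singles = lapply(df$mutation, parse_mutations, parent_id = parent_id),
       ddg = df$ddG)
}
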