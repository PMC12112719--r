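#' Pose-triage configuration
#'
#' Thresholds driving the docking funnel: the interface contact cutoff, the
#' diversity radius used when clustering poses by ligand RMSD, the maximum
#' number of poses retained, and the top-k sizes used when averaging
#' binding energies at the docking and refinement stages.
#'
#' @param contact_cutoff Calpha-Calpha contact distance defining patch
#'   proximity (Angstrom, default 10).
#' @param diversity_rmsd Minimum ligand RMSD separating two kept poses
#'   (Angstrom, default 2).
#' @param max_kept_poses Cap on poses retained by greedy clustering
#'   (default 50).
#' @param docking_top_k,pele_top_k Top-k sizes for mean binding energy at
#'   the docking and refinement stages (defaults 50 and 10).
#' @param exclusion_patch Optional receptor residue set (see
#'   \code{\link{interface_patch}}) near which ligand contacts disqualify a
#'   pose, e.g. a dimerisation surface.
#' @return A list of class \code{"triage_config"}.
#' @export
triage_config <- function(contact_cutoff = 10, diversity_rmsd = 2,
                          max_kept_poses = 50L, docking_top_k = 50L,
                          pele_top_k = 10L, exclusion_patch = NULL) {
  vals <- c(contact_cutoff, diversity_rmsd, max_kept_poses,
            docking_top_k, pele_top_k)
  if (any(vals <= 0)) abort_input("triage thresholds must be positive")
  structure(list(contact_cutoff = contact_cutoff,
                 diversity_rmsd = diversity_rmsd,
                 max_kept_poses = as.integer(max_kept_poses),
                 docking_top_k = as.integer(docking_top_k),
                 pele_top_k = as.integer(pele_top_k),
                 exclusion_patch = exclusion_patch),
            class = "triage_config")
}

#' Define an interface patch
#'
#' A predicted interacting region on one binding partner: a set of author
#' residue indices on a named chain set.
#'
#' @param role \code{"receptor"} or \code{"ligand"}.
#' @param residues Integer vector of 1-based author residue numbers.
#' @param chain Optional chain restriction (default: any chain).
#' @return A list of class \code{"interface_patch"}.
#' @export
interface_patch <- function(role = c("receptor", "ligand"), residues,
                            chain = NULL) {
  role <- match.arg(role)
  if (length(residues) == 0L) abort_input("patch must be non-empty")
  structure(list(role = role, residues = as.integer(residues), chain = chain),
            class = "interface_patch")
}

# Calpha coordinates of a patch; errors if any residue is absent.
patch_xyz <- function(s, patch) {
  ca <- s[s$elety == "CA", ]
  if (!is.null(patch$chain)) ca <- ca[ca$chain %in% patch$chain, ]
  missing <- setdiff(patch$residues, ca$resno)
  if (length(missing))
    abort_input("patch residues absent from structure: ",
                paste(missing, collapse = ", "))
  as.matrix(ca[ca$resno %in% patch$residues, c("x", "y", "z")])
}

min_pair_dist <- function(a, b) {
  # smallest Euclidean distance between rows of a and rows of b
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Filter poses by interface-patch proximity
#'
#' Keeps a pose iff at least one Calpha of the receptor patch lies within
#' the contact cutoff of some Calpha of the ligand patch (distance exactly
#' at the cutoff counts as in contact). When an exclusion patch is
#' configured, poses whose ligand has any Calpha within the cutoff of that
#' receptor region are additionally discarded.
#'
#' @param deck A \code{\link{pose_deck}}.
#' @param receptor_patch,ligand_patch \code{\link{interface_patch}}
#'   objects.
#' @param cfg A \code{\link{triage_config}}.
#' @return A \code{pose_deck} containing the kept poses, in input order.
#' @export
interface_filter <- function(deck, receptor_patch, ligand_patch,
                             cfg = triage_config()) {
  keep <- vapply(deck$poses, function(p) {
    rp <- patch_xyz(p$receptor, receptor_patch)
    lp <- patch_xyz(p$ligand, ligand_patch)
    ok <- min_pair_dist(rp, lp) <= cfg$contact_cutoff
    if (ok && !is.null(cfg$exclusion_patch)) {
      ex <- patch_xyz(p$receptor, cfg$exclusion_patch)
      lig_all <- st_xyz(p$ligand, "calpha")
      if (min_pair_dist(ex, lig_all) <= cfg$contact_cutoff) ok <- FALSE
    }
    ok
  }, NA)
  if (!any(keep)) abort_input("no pose passes the interface filter")
  pose_deck(deck$poses[keep])
}

#' Greedy energy/diversity pose clustering
#'
#' Iterative leader clustering that balances energetic relevance with
#' conformational diversity: poses are visited in order of ascending score
#' (best first; ties broken by pose id) and a pose is kept iff its ligand
#' RMSD to every already-kept pose is strictly greater than the diversity
#' radius. Selection stops once \code{max_kept_poses} poses are kept or
#' the deck is exhausted.
#'
#' @param deck A \code{\link{pose_deck}}.
#' @param cfg A \code{\link{triage_config}}.
#' @return A \code{pose_deck} of kept poses, sorted by score.
#' @export
greedy_diverse_top <- function(deck, cfg = triage_config()) {
  poses <- deck$poses
  scores <- vapply(poses, `[[`, 0, "score")
  ids <- vapply(poses, `[[`, "", "id")
  ord <- order(scores, ids)
  kept <- list()
  for (i in ord) {
    cand <- poses[[i]]
    diverse <- all(vapply(kept, function(k)
      ligand_rmsd(k, cand) > cfg$diversity_rmsd, NA))
    if (diverse) {
      kept[[length(kept) + 1L]] <- cand
      if (length(kept) >= cfg$max_kept_poses) break
    }
  }
  pose_deck(kept)
}

#' Mean of the k best binding-energy scores
#'
#' Averages the k lowest (most favourable) scores; when fewer than k are
#' available all scores are averaged. This is the per-candidate summary
#' statistic used at both funnel stages (docking, k = 50; refinement,
#' k = 10).
#'
#' @param scores Numeric vector of binding-energy scores.
#' @param k Number of best scores to average.
#' @return Scalar mean.
#' @export
mean_top_k <- function(scores, k) {
  if (length(scores) == 0L) abort_input("no scores supplied")
  mean(sort(scores)[seq_len(min(k, length(scores)))])
}

#' Cross-candidate mean-energy selection
#'
#' Discards every candidate whose mean binding energy is strictly higher
#' (less favourable) than the arithmetic mean over all candidates;
#' candidates exactly at the mean survive, so at least one candidate is
#' always kept.
#'
#' @param candidate_scores Named numeric vector mapping candidate id to
#'   mean binding energy.
#' @return A list with \code{kept} (names), \code{mean} (the cross-system
#'   mean) and \code{report} (data frame: \code{candidate}, \code{score},
#'   \code{kept}).
#' @export
funnel_select <- function(candidate_scores) {
  if (length(candidate_scores) == 0L) abort_input("no candidates supplied")
  mu <- mean(candidate_scores)
  keep <- candidate_scores <= mu
  report <- data.frame(candidate = names(candidate_scores),
                       score = as.numeric(candidate_scores),
                       kept = as.logical(keep), stringsAsFactors = FALSE)
  list(kept = names(candidate_scores)[keep], mean = mu, report = report)
}

#' Read interface patches from a plain-text residue list
#'
#' One residue per line in \code{chain:index} form (e.g. \code{A:17});
#' lines starting with \code{#} are ignored.
#'
#' @param path File path.
#' @param role Patch role, \code{"receptor"} or \code{"ligand"}.
#' @return An \code{\link{interface_patch}}.
#' @export
read_patch <- function(path, role = c("receptor", "ligand")) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, ":", fixed = TRUE)
  chains <- vapply(parts, `[`, "", 1L)
  res <- as.integer(vapply(parts, `[`, "", 2L))
  interface_patch(match.arg(role), res, chain = unique(chains))
}
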