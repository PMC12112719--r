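#' Energetics configuration
#'
#' Thresholds and defaults for end-state binding-energy post-processing:
#' the hotspot threshold on per-residue contributions, the number of
#' trajectory snapshots conventionally analysed, and the quantile fractions
#' used when banding candidates into weak/medium/strong groups.
#'
#' @param hotspot_threshold Per-residue energy below which a residue is a
#'   binding hotspot (kcal/mol, default -2).
#' @param n_snapshots Conventional number of snapshots per trajectory
#'   (default 500); informational, frame selection is the caller's
#'   responsibility.
#' @param band_fractions Length-3 non-negative weights for the
#'   \{NB/WB, MB, SB\} bands (default equal terciles); normalised
#'   internally.
#' @return A list of class \code{"energetics_config"}.
#' @export
energetics_config <- function(hotspot_threshold = -2, n_snapshots = 500L,
                              band_fractions = c(1, 1, 1) / 3) {
  if (length(band_fractions) != 3L || any(band_fractions < 0) ||
      sum(band_fractions) == 0)
    abort_input("band_fractions must be 3 non-negative weights")
  structure(list(hotspot_threshold = hotspot_threshold,
                 n_snapshots = as.integer(n_snapshots),
                 band_fractions = band_fractions / sum(band_fractions)),
            class = "energetics_config")
}

#' Snapshot-averaged binding free energy
#'
#' End-state estimate from per-frame molecular-mechanics plus
#' implicit-solvation energies: for every frame
#' \eqn{\Delta G_t = E_{complex} - E_{receptor} - E_{ligand}}, and the
#' estimate is the mean over frames with its standard error.
#' Conformational entropy is excluded by construction.
#'
#' @param frames Data frame with numeric columns \code{E_complex},
#'   \code{E_receptor}, \code{E_ligand} (kcal/mol, one row per snapshot,
#'   each component already including its solvation term).
#' @return A list with \code{dG} (kcal/mol), \code{se} (standard error of
#'   the mean) and \code{per_frame} (numeric vector).
#' @export
binding_dg <- function(frames) {
  need <- c("E_complex", "E_receptor", "E_ligand")
  if (!is.data.frame(frames) || nrow(frames) == 0L ||
      !all(need %in% names(frames)))
    abort_input("frames must be a non-empty data frame with columns ",
                paste(need, collapse = ", "))
  dg <- frames$E_complex - frames$E_receptor - frames$E_ligand
  if (any(!is.finite(dg))) abort_input("non-finite energy component")
  se <- if (length(dg) > 1L) stats::sd(dg) / sqrt(length(dg)) else 0
  list(dG = mean(dg), se = se, per_frame = dg)
}

#' Relative binding energy between a variant and its parent hit
#'
#' \eqn{\Delta\Delta G = \Delta G_{variant} - \Delta G_{parent}}; a
#' negative value predicts improved binding affinity.
#'
#' @param variant_dg,original_dg Binding free energies (kcal/mol).
#' @return \eqn{\Delta\Delta G} in kcal/mol.
#' @examples
#' ddg(-45.2, -40.0)
#' @export
ddg <- function(variant_dg, original_dg) {
  if (!all(is.finite(c(variant_dg, original_dg))))
    abort_input("binding energies must be finite")
  variant_dg - original_dg
}

#' Construct a per-residue decomposition table
#'
#' Each interface residue's contribution to binding is its summed pairwise
#' interaction energy over all residues in the system.
#'
#' @param chain Character vector of chain identifiers.
#' @param resno Integer vector of author residue numbers (unique per
#'   chain).
#' @param dGres Numeric contributions (kcal/mol).
#' @param resname Optional residue names.
#' @return A data frame of class \code{"decomposition_table"}.
#' @export
decomposition_table <- function(chain, resno, dGres, resname = NA_character_) {
  n <- length(dGres)
  out <- data.frame(chain = rep_len(as.character(chain), n),
                    resno = rep_len(as.integer(resno), n),
                    resname = rep_len(as.character(resname), n),
                    dGres = as.numeric(dGres), stringsAsFactors = FALSE)
  if (anyDuplicated(paste(out$chain, out$resno)))
    abort_input("duplicate residues in decomposition table")
  if (any(!is.finite(out$dGres))) abort_input("dGres must be finite")
  class(out) <- c("decomposition_table", "data.frame")
  out
}

#' Binding hotspots of a decomposition table
#'
#' Residues contributing strongly to binding: per-residue energy strictly
#' below the threshold (default -2 kcal/mol). A residue exactly at the
#' threshold is not a hotspot.
#'
#' @param table A \code{\link{decomposition_table}}.
#' @param cfg An \code{\link{energetics_config}}.
#' @return The hotspot rows of \code{table}.
#' @export
hotspots <- function(table, cfg = energetics_config()) {
  out <- table[table$dGres < cfg$hotspot_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mutable interface positions for affinity maturation
#'
#' The complement of the hotspot rule on a chosen interface set: interface
#' residues whose contribution is at or above the threshold are considered
#' energetically dispensable and hence candidates for mutagenesis.
#' Hotspots and mutable positions partition the interface.
#'
#' @param table A \code{\link{decomposition_table}}.
#' @param interface_residues Integer vector of author residue numbers (all
#'   must appear in the table).
#' @param cfg An \code{\link{energetics_config}}.
#' @param chain Optional chain restriction.
#' @return The mutable rows of \code{table}, restricted to the interface.
#' @export
mutable_positions <- function(table, interface_residues,
                              cfg = energetics_config(), chain = NULL) {
  tab <- table
  if (!is.null(chain)) tab <- tab[tab$chain %in% chain, , drop = FALSE]
  missing <- setdiff(interface_residues, tab$resno)
  if (length(missing))
    abort_input("interface residues missing from table: ",
                paste(missing, collapse = ", "))
  tab <- tab[tab$resno %in% interface_residues, , drop = FALSE]
  out <- tab[tab$dGres >= cfg$hotspot_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Band candidates into strength groups by binding energy
#'
#' Ranks candidates by snapshot-averaged binding energy (most negative =
#' strongest) and splits them into \{NB/WB, MB, SB\} groups by the
#' configured quantile fractions: the strongest fraction becomes SB, the
#' weakest becomes NB/WB. Group sizes are the fraction boundaries rounded
#' to candidate counts and always sum to the number of candidates; ties
#' are broken by candidate id, so the banding is order invariant.
#'
#' @param dg_by_candidate Named numeric vector of binding energies
#'   (kcal/mol).
#' @param cfg An \code{\link{energetics_config}}; the band fractions are
#'   read in \{NB/WB, MB, SB\} order.
#' @return A data frame with columns \code{candidate}, \code{dG},
#'   \code{band}, sorted strongest first.
#' @export
band_candidates <- function(dg_by_candidate, cfg = energetics_config()) {
  n <- length(dg_by_candidate)
  if (n < 3L) abort_input("banding needs at least 3 candidates")
  if (is.null(names(dg_by_candidate)))
    names(dg_by_candidate) <- sprintf("cand_%d", seq_len(n))
  ord <- order(dg_by_candidate, names(dg_by_candidate))
  # strongest first; fractions are given weakest band first
  sizes <- diff(c(0L, round(cumsum(rev(cfg$band_fractions)) * n)))
  sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
  band <- rep(c("SB", "MB", "NB/WB"), times = sizes)
  data.frame(candidate = names(dg_by_candidate)[ord],
             dG = as.numeric(dg_by_candidate[ord]),
             band = band, stringsAsFactors = FALSE)
}

#' Read per-frame energy components from CSV
#'
#' Expects columns \code{frame}, \code{E_complex}, \code{E_receptor},
#' \code{E_ligand}.
#'
#' @param path CSV path.
#' @param frame_range Optional length-2 integer vector restricting the
#'   frames analysed (inclusive); default: all frames.
#' @return A data frame usable with \code{\link{binding_dg}}.
#' @export
read_energy_frames <- function(path, frame_range = NULL) {
  df <- utils::read.csv(path)
  need <- c("frame", "E_complex", "E_receptor", "E_ligand")
  if (!all(need %in% names(df)))
    abort_input("energy CSV needs columns ", paste(need, collapse = ", "))
  if (!is.null(frame_range))
    df <- df[df$frame >= frame_range[1] & df$frame <= frame_range[2], ]
  df
}

#' Read a per-residue decomposition table from CSV
#'
#' Expects columns \code{chain}, \code{resid}, \code{resname},
#' \code{dGres} (column-compatible with common end-state post-processor
#' exports).
#'
#' @param path CSV path.
#' @return A \code{\link{decomposition_table}}.
#' @export
read_decomposition_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("chain", "resid", "dGres")
  if (!all(need %in% names(df)))
    abort_input("decomposition CSV needs columns ",
                paste(need, collapse = ", "))
  decomposition_table(df$chain, df$resid, df$dGres,
                      if ("resname" %in% names(df)) df$resname else NA)
}
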