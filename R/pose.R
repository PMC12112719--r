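#' Construct a docking pose
#'
#' A pose pairs a (fixed) receptor structure with one rigid placement of
#' the ligand protein and the scalar binding-energy score assigned by the
#' docking stage (lower is better).
#'
#' @param id Pose identifier.
#' @param receptor,ligand \code{\link{ca_structure}} models.
#' @param score Binding-energy score (arbitrary energy units, lower =
#'   better).
#' @return A list of class \code{"pose"}.
#' @export
pose <- function(id, receptor, ligand, score) {
  stopifnot(inherits(receptor, "ca_structure"), inherits(ligand, "ca_structure"))
  if (!is.finite(score)) abort_input("pose score must be finite")
  structure(list(id = as.character(id), receptor = receptor,
                 ligand = ligand, score = as.numeric(score)),
            class = "pose")
}

#' Construct a pose deck
#'
#' @param poses List of \code{\link{pose}} objects sharing one receptor
#'   and one ligand composition (equal ligand residue counts).
#' @return A list of class \code{"pose_deck"}.
#' @export
pose_deck <- function(poses) {
  if (length(poses) == 0L) abort_input("empty pose deck")
  nres <- vapply(poses, function(p) sum(p$ligand$elety == "CA"), 0L)
  if (length(unique(nres)) != 1L)
    abort_input("ligand residue count must be constant across the deck")
  structure(list(poses = poses), class = "pose_deck")
}

#' Ligand RMSD between two poses of one deck
#'
#' Superposes the second pose's receptor onto the first pose's receptor
#' (Kabsch on the selected atoms), applies that transform to the second
#' ligand, and returns the plain coordinate RMSD between the two ligand
#' copies with no further superposition. This measures how far apart two
#' binding modes are in the receptor frame; it is symmetric and invariant
#' to rigid motions applied jointly to either pose.
#'
#' @param p,q \code{\link{pose}} objects with matching receptor and ligand
#'   compositions.
#' @param selection Atom selection, \code{"calpha"} (default) or
#'   \code{"backbone"}.
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(p, q, selection = c("calpha", "backbone")) {
  selection <- match.arg(selection)
  lp <- st_xyz(p$ligand, selection); lq <- st_xyz(q$ligand, selection)
  if (nrow(lp) != nrow(lq))
    abort_input("mismatched ligand atom counts between poses")
  rp <- st_xyz(p$receptor, selection); rq <- st_xyz(q$receptor, selection)
  if (nrow(rp) != nrow(rq))
    abort_input("mismatched receptor atom counts between poses")
  tr <- kabsch_superpose(rq, rp)
  plain_rmsd(apply_transform(lq, tr), lp)
}

#' Per-frame ligand RMSD of a simulation trajectory
#'
#' Computes the ligand RMSD of every trajectory frame against a reference
#' frame, after superposing receptors frame by frame. Used to summarise
#' the stability of a bound pose along a simulation.
#'
#' @param frames List of \code{\link{pose}} objects (one per frame, same
#'   topology as the reference).
#' @param reference Reference \code{\link{pose}}.
#' @param selection Atom selection, \code{"calpha"} (default) or
#'   \code{"backbone"}.
#' @return A list with \code{series} (numeric, one value per frame),
#'   \code{mean} and \code{max}.
#' @export
trajectory_lrmsd <- function(frames, reference,
                             selection = c("calpha", "backbone")) {
  selection <- match.arg(selection)
  series <- vapply(frames, function(f) ligand_rmsd(reference, f, selection), 0)
  list(series = series, mean = mean(series), max = max(series))
}

#' Write a pose deck to a directory
#'
#' Writes the shared receptor and one PDB per ligand pose, plus a TSV
#' manifest (\code{pose_id}, \code{file}, \code{score}).
#'
#' @param deck A \code{\link{pose_deck}}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_pose_deck <- function(deck, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ca_structure(deck$poses[[1]]$receptor, file.path(dir, "receptor.pdb"))
  files <- vapply(deck$poses, function(p) {
    f <- paste0("pose_", p$id, ".pdb")
    write_ca_structure(p$ligand, file.path(dir, f))
    f
  }, "")
  manifest <- data.frame(
    pose_id = vapply(deck$poses, `[[`, "", "id"),
    file = files,
    score = vapply(deck$poses, `[[`, 0, "score"),
    stringsAsFactors = FALSE)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mpath)
}

#' Read a pose deck from a directory
#'
#' Counterpart of \code{\link{write_pose_deck}}: expects
#' \code{receptor.pdb}, per-pose ligand PDBs and \code{manifest.tsv}.
#'
#' @param dir Deck directory.
#' @return A \code{\link{pose_deck}}.
#' @export
read_pose_deck <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"),
                                sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  receptor <- read_ca_structure(file.path(dir, "receptor.pdb"))
  poses <- lapply(seq_len(nrow(manifest)), function(i) {
    pose(manifest$pose_id[i], receptor,
         read_ca_structure(file.path(dir, manifest$file[i])),
         manifest$score[i])
  })
  pose_deck(poses)
}
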