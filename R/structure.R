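#' Construct a reduced structure model
#'
#' The package's structural container: an ordered table of protein atoms
#' (by default one Calpha per residue) with chain identifiers, 1-based
#' author residue numbering, coordinates in Angstrom and an optional
#' per-residue confidence (pLDDT) value.
#'
#' @param chain Character vector of chain identifiers.
#' @param resno Integer vector of author residue numbers, strictly
#'   increasing within each chain (per atom type).
#' @param resname Character vector of 3-letter residue names.
#' @param xyz Numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom).
#' @param elety Atom names (default all \code{"CA"}); backbone models use
#'   \code{N, CA, C, O}.
#' @param plddt Optional numeric per-atom confidence in [0, 100].
#' @return A data frame of class \code{"ca_structure"}.
#' @export
ca_structure <- function(chain, resno, resname, xyz, elety = "CA",
                         plddt = NA_real_) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (ncol(xyz) != 3L || n == 0L) abort_input("xyz must be an n x 3 matrix")
  out <- data.frame(chain = rep_len(as.character(chain), n),
                    resno = rep_len(as.integer(resno), n),
                    resname = rep_len(as.character(resname), n),
                    elety = rep_len(as.character(elety), n),
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    plddt = rep_len(as.numeric(plddt), n),
                    stringsAsFactors = FALSE)
  ca <- out[out$elety == "CA", ]
  for (ch in unique(ca$chain)) {
    r <- ca$resno[ca$chain == ch]
    if (anyDuplicated(r) || is.unsorted(r, strictly = TRUE))
      abort_input("residue numbers must be strictly increasing within chain ", ch)
  }
  class(out) <- c("ca_structure", "data.frame")
  out
}

# Coordinate matrix for an atom selection ("calpha" or "backbone"),
# chains concatenated in their order of appearance.
st_xyz <- function(s, selection = c("calpha", "backbone")) {
  selection <- match.arg(selection)
  keep <- if (selection == "calpha") s$elety == "CA"
          else s$elety %in% c("N", "CA", "C", "O")
  as.matrix(s[keep, c("x", "y", "z")])
}

# One-letter sequence of the Calpha trace.
st_sequence <- function(s) {
  ca <- s[s$elety == "CA", ]
  paste(bio3d::aa321(ca$resname), collapse = "")
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' two paired point sets; reflections are excluded. The transform maps
#' \code{mobile} onto \code{fixed} as \code{mobile \%*\% rotation + t(translation)}.
#'
#' @param mobile,fixed Numeric n x 3 matrices with matching rows, n >= 3.
#' @return A list with \code{rotation} (3 x 3), \code{translation}
#'   (length 3) and \code{rmsd} (Angstrom, at the optimum).
#' @export
kabsch_superpose <- function(mobile, fixed) {
  mobile <- as.matrix(mobile); fixed <- as.matrix(fixed)
  if (nrow(mobile) != nrow(fixed) || ncol(mobile) != 3L || ncol(fixed) != 3L)
    abort_input("point sets must be matched n x 3 matrices")
  if (nrow(mobile) < 3L) abort_input("need at least 3 points")
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  x <- sweep(mobile, 2, cm); y <- sweep(fixed, 2, cf)
  sv <- svd(crossprod(x, y))
  d <- sign(det(sv$u) * det(sv$v))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  moved <- x %*% rot
  rmsd <- sqrt(mean(rowSums((moved - y)^2)))
  list(rotation = rot, translation = as.numeric(cf - cm %*% rot), rmsd = rmsd)
}

# Apply a kabsch_superpose transform to an n x 3 coordinate matrix.
apply_transform <- function(xyz, transform) {
  sweep(as.matrix(xyz) %*% transform$rotation, 2, transform$translation, `+`)
}

# Plain RMSD between paired coordinate sets, no superposition.
plain_rmsd <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

#' Alignment-guided Calpha RMSD between homologous structures
#'
#' Globally aligns the two Calpha-trace sequences (BLOSUM62, affine gaps),
#' takes the Calpha pairs at mutually aligned columns (gap columns are
#' skipped), superposes them with \code{\link{kabsch_superpose}} and
#' returns the optimal RMSD. This is the standard way to compare predicted
#' models of related but non-identical sequences.
#'
#' @param a,b \code{\link{ca_structure}} models.
#' @param params \code{\link{alignment_params}}.
#' @return RMSD in Angstrom.
#' @export
aligned_ca_rmsd <- function(a, b, params = alignment_params()) {
  al <- align_pair(st_sequence(a), st_sequence(b), params)
  ca_a <- strsplit(al$a, "")[[1]]
  ca_b <- strsplit(al$b, "")[[1]]
  ia <- cumsum(ca_a != "-")
  ib <- cumsum(ca_b != "-")
  both <- ca_a != "-" & ca_b != "-"
  if (sum(both) < 3L)
    abort_input("degenerate alignment: fewer than 3 matched residue pairs")
  xa <- st_xyz(a, "calpha")[ia[both], , drop = FALSE]
  xb <- st_xyz(b, "calpha")[ib[both], , drop = FALSE]
  kabsch_superpose(xa, xb)$rmsd
}

#' Read a reduced structure model from a PDB file
#'
#' Parses ATOM records (HETATM ignored), keeps backbone atoms
#' (N, CA, C, O) with the first-listed alternate location, and carries the
#' B-factor column of the Calpha atoms as a pLDDT confidence track when
#' present.
#'
#' @param path PDB file path.
#' @return A \code{\link{ca_structure}}.
#' @export
read_ca_structure <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM" &
                   pdb$atom$elety %in% c("N", "CA", "C", "O"), ]
  # first alternate location wins
  key <- paste(at$chain, at$resno, at$elety)
  at <- at[!duplicated(key), ]
  ca_structure(chain = at$chain, resno = at$resno, resname = at$resid,
               xyz = as.matrix(at[, c("x", "y", "z")]),
               elety = at$elety, plddt = at$b)
}

#' Write a reduced structure model to a PDB file
#'
#' @param s A \code{\link{ca_structure}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_ca_structure <- function(s, path) {
  b <- ifelse(is.na(s$plddt), 0, s$plddt)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(s[, c("x", "y", "z")]))),
                   resno = s$resno, resid = s$resname, chain = s$chain,
                   elety = s$elety, b = b)
  invisible(path)
}
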