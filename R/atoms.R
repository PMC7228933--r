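#' Atomic coordinate set
#'
#' Lightweight container for a protein model: element symbols, coordinates
#' in Angstrom and residue/chain labels.
#'
#' @param xyz numeric matrix (n x 3), Angstrom.
#' @param element character vector of element symbols.
#' @param resid,resno,chain optional per-atom labels.
#' @return an object of class `atom_set`.
#' @export
atom_set <- function(xyz, element, resid = NULL, resno = NULL, chain = NULL) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) == 0) stop("empty atom set")
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  if (length(element) != nrow(xyz)) stop("element length mismatch")
  structure(list(xyz = xyz, element = toupper(element),
                 resid = resid, resno = resno, chain = chain),
            class = "atom_set")
}

#' @export
print.atom_set <- function(x, ...) {
  cat(sprintf("atom_set: %d atoms (%s)\n", nrow(x$xyz),
              paste(names(sort(table(x$element), decreasing = TRUE)), collapse = " ")))
  invisible(x)
}

water_resids <- c("HOH", "WAT", "DOD", "SOL", "H2O")

#' Read a protein model from a PDB file
#'
#' Loads ATOM records from the first MODEL of a PDB file (via bio3d).
#' Alternate locations keep the blank or 'A' copy only; waters and, by
#' default, hydrogens are excluded. The element is taken from the element
#' column when present, otherwise inferred from the atom name.
#'
#' @param path PDB file.
#' @param keep_hydrogens keep hydrogen atoms (default `FALSE`).
#' @return an [atom_set()].
#' @export
read_atoms <- function(path, keep_hydrogens = FALSE) {
  if (!file.exists(path)) stop("cannot read PDB: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  a <- a[!(a$resid %in% water_resids), , drop = FALSE]
  if (nrow(a) == 0) stop("no protein atoms: file has no usable ATOM records")
  alt <- a$alt
  alt[is.na(alt)] <- ""
  a <- a[alt %in% c("", "A"), , drop = FALSE]
  elem <- a$elesy
  miss <- is.na(elem) | !nzchar(trimws(elem))
  if (any(miss)) {
    # atom-name heuristic: first alphabetic character that is not a digit
    guess <- sub("^[0-9]*", "", trimws(a$elety[miss]))
    elem[miss] <- substr(guess, 1, 1)
  }
  elem <- toupper(trimws(elem))
  if (!keep_hydrogens) {
    keep <- elem != "H"
    a <- a[keep, , drop = FALSE]
    elem <- elem[keep]
  }
  if (nrow(a) == 0) stop("no protein atoms after filtering")
  atom_set(cbind(a$x, a$y, a$z), elem,
           resid = a$resid, resno = a$resno, chain = a$chain)
}

#' Write an atom set as a PDB file
#'
#' Minimal PDB writer for synthetic/toy models; round-trips through
#' [read_atoms()].
#'
#' @param atoms an [atom_set()].
#' @param path destination file.
#' @export
write_atoms <- function(atoms, path) {
  n <- nrow(atoms$xyz)
  resid <- atoms$resid %||% rep("ALA", n)
  resno <- atoms$resno %||% rep(1L, n)
  chain <- atoms$chain %||% rep("A", n)
  name <- attr(atoms, "atom_names") %||% atoms$element
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(n) %% 100000, substr(name, 1, 4), substr(resid, 1, 3),
    substr(chain, 1, 1), as.integer(resno) %% 10000,
    atoms$xyz[, 1], atoms$xyz[, 2], atoms$xyz[, 3], atoms$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Align an atom set to its principal axes
#'
#' Moves the centroid to the origin and rotates so the longest principal
#' axis of inertia lies along z (the membrane normal convention used
#' throughout the modeling machinery). The rotation is right-handed.
#'
#' @param atoms an [atom_set()] (or bare n x 3 matrix).
#' @return same type as input, transformed; the 3 x 3 rotation is attached
#'   as attribute `"rotation"`.
#' @export
align_principal_axes <- function(atoms) {
  xyz <- if (inherits(atoms, "atom_set")) atoms$xyz else as.matrix(atoms)
  ctr <- colMeans(xyz)
  x0 <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(x0) / nrow(x0), symmetric = TRUE)
  # columns ordered by decreasing variance; longest axis -> z
  rot <- ev$vectors[, c(2, 3, 1)]
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  out_xyz <- x0 %*% rot
  if (inherits(atoms, "atom_set")) {
    atoms$xyz <- out_xyz
    attr(atoms, "rotation") <- rot
    atoms
  } else {
    attr(out_xyz, "rotation") <- rot
    out_xyz
  }
}

#' Read a one-letter amino-acid sequence from FASTA
#'
#' @param path FASTA file; the first record is used.
#' @return single uppercase string of one-letter codes.
#' @export
read_sequence <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  if (length(seqs) == 0) stop("no sequences in ", path)
  toupper(as.character(seqs[[1]]))
}

#' Electron count and volume of a protein sequence
#'
#' Sums residue electrons (from residue formulae) and mean residue volumes
#' over a one-letter sequence; used for the protein electron density and
#' for molecular-weight based size estimates.
#'
#' @param sequence one-letter amino-acid string.
#' @return list with `electrons`, `volume` (A^3), `mw` (Da), `density`
#'   (e-/A^3).
#' @export
sequence_composition <- function(sequence) {
  res <- ms_table("residues")
  aa <- strsplit(toupper(gsub("[^A-Za-z]", "", sequence)), "")[[1]]
  unknown <- setdiff(aa, res$code1)
  if (length(unknown))
    stop("unknown residue code(s): ", paste(unique(unknown), collapse = ""))
  idx <- match(aa, res$code1)
  el <- vapply(res$formula, electron_count, numeric(1))
  # residue masses from formulas: electrons ~ Z; mass needs atomic weights --
  # use the standard average residue mass approximation 110 Da only as a
  # fallback; compute from formula with integer mass numbers instead
  amass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)
  mass1 <- vapply(res$formula, function(f) {
    cc <- parse_chemical_formula(f)
    sum(amass[names(cc)] * as.numeric(cc))
  }, numeric(1))
  electrons <- sum(el[idx])
  volume <- sum(res$volume[idx])
  mw <- sum(mass1[idx]) + 18.02   # add terminal water
  list(electrons = electrons, volume = volume, mw = mw,
       density = electrons / volume)
}
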