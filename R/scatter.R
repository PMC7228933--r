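#' Multi-phase scattering body
#'
#' A set of scattering points (pseudo-atoms or beads), each with a volume
#' and a phase label; each phase carries one excess electron density
#' (contrast). The point form-factor radius gives every point the
#' amplitude of a homogeneous sphere of that radius.
#'
#' @param xyz n x 3 coordinates (A).
#' @param volume per-point volumes (A^3), scalar recycled.
#' @param phase character vector of phase labels.
#' @param contrast named vector of contrasts (e-/A^3) covering every label.
#' @param radius point form-factor radius (A).
#' @param spacing lattice spacing used to generate the points, if any.
#' @return object of class `scattering_body`.
#' @export
scattering_body <- function(xyz, volume, phase, contrast, radius = 0,
                            spacing = NULL) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) == 0) stop("empty body")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  volume <- rep_len(volume, nrow(xyz))
  if (any(volume <= 0)) stop("volumes must be positive")
  phase <- as.character(rep_len(phase, nrow(xyz)))
  missing <- setdiff(unique(phase), names(contrast))
  if (length(missing))
    stop("phase without contrast: ", paste(missing, collapse = ", "))
  structure(list(xyz = xyz, volume = volume, phase = phase,
                 contrast = contrast, radius = radius, spacing = spacing),
            class = "scattering_body")
}

#' @export
print.scattering_body <- function(x, ...) {
  cat(sprintf("scattering_body: %d points, phases: %s\n", nrow(x$xyz),
              paste(sprintf("%s(%d)", names(table(x$phase)), table(x$phase)),
                    collapse = " ")))
  invisible(x)
}

body_weights <- function(body) body$contrast[body$phase] * body$volume

#' Debye-formula scattering intensity of a body
#'
#' `I(s) = sum_ij g_i g_j Phi^2(s r0) sinc(s d_ij)` with `g_i` the contrast
#' times volume of point i and `Phi` the sphere form-factor amplitude of
#' the point radius. Pair distances are binned into a histogram (width
#' `min(pi/(32 s_max), spacing/2)` by default) for cost control; each bin
#' is evaluated at its weighted mean distance with a curvature correction,
#' and the forward limit `I(0) = (sum g)^2` and the self term are exact.
#'
#' @param body a [scattering_body()].
#' @param s momentum-transfer grid (A^-1, ascending, >= 0).
#' @param binned use the histogram approximation (default) or the exact
#'   O(N^2) sum.
#' @param bin_width histogram bin width override (A).
#' @return a [saxs_profile()] when `min(s) > 0`, otherwise a plain list
#'   with `s` and `intensity` (profiles require an ascending positive
#'   grid of length >= 2).
#' @export
debye_intensity <- function(body, s, binned = TRUE, bin_width = NULL) {
  if (is.unsorted(s, strictly = TRUE)) stop("s grid must be ascending")
  g <- body_weights(body)
  if (is.null(bin_width)) {
    bw_s <- pi / (32 * max(s, 0.01))
    bin_width <- if (!is.null(body$spacing)) min(bw_s, body$spacing / 2) else bw_s
  }
  I <- if (binned) {
    debye_binned_cpp(body$xyz, g, body$radius, s, bin_width)
  } else {
    debye_exact_cpp(body$xyz, g, body$radius, s)
  }
  list(s = s, intensity = I)
}

#' Fill the detergent corona around an aligned atomic model
#'
#' The protein atoms (assumed centered with the membrane normal along z;
#' see [align_principal_axes()]) become phase-protein points with
#' per-element displaced-solvent volumes. A lattice at the given spacing
#' fills the hydrocarbon tail torus — height `a`, in-plane extent `b`
#' (semi-axes scaled by the ellipticity e) around the protein's
#' transmembrane cross-section — and the head shell of thickness `t`
#' wrapped around it. Lattice points within the exclusion radius
#' (1.7 A + spacing/2) of any protein atom are removed.
#'
#' @param atoms an [atom_set()], aligned.
#' @param geom a [corona_geometry()][corona_start] (fields a, b, e, t).
#' @param contrasts a [phase_densities()] contrast set.
#' @param spacing lattice spacing (A), default 3.
#' @return a [scattering_body()] with phases `protein`, `tails`, `heads`.
#' @export
fill_corona <- function(atoms, geom, contrasts, spacing = 3) {
  xyz <- atoms$xyz
  a <- geom$a; b <- geom$b; e <- geom$e; t <- geom$t
  # transmembrane cross-section radius of the protein (robust max)
  slab <- abs(xyz[, 3]) <= a / 2
  rho_at <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  R_in <- if (any(slab)) quantile(rho_at[slab], 0.98) else quantile(rho_at, 0.98)
  R_in <- as.numeric(R_in)
  Rout_x <- R_in + b * e; Rout_y <- R_in + b / e
  ext <- max(Rout_x, Rout_y) + t + spacing
  zmax <- a / 2 + t + spacing
  gx <- seq(-ext, ext, by = spacing)
  gz <- seq(-zmax, zmax, by = spacing)
  grid <- as.matrix(expand.grid(x = gx, y = gx, z = gz))
  # elliptical radial coordinate relative to the outer tail surface
  rho_e <- sqrt((grid[, 1] / e)^2 + (grid[, 2] * e)^2)
  in_tail <- abs(grid[, 3]) <= a / 2 & rho_e <= R_in + b
  d_out <- pmax(rho_e - (R_in + b), 0)
  d_z <- pmax(abs(grid[, 3]) - a / 2, 0)
  dist_out <- sqrt(d_out^2 + d_z^2)
  in_head <- !in_tail & dist_out <= t & rho_e >= R_in * 0.8
  cand <- in_tail | in_head
  grid <- grid[cand, , drop = FALSE]
  lab <- ifelse(in_tail[cand], "tails", "heads")
  excl <- 1.7 + spacing / 2
  clash <- points_near_cpp(grid, xyz, excl)
  grid <- grid[!clash, , drop = FALSE]
  lab <- lab[!clash]
  if (nrow(grid) == 0) stop("corona region contains no points")
  av <- ms_table("atom_volumes")
  vols <- setNames(av$volume, av$element)
  atom_vol <- vols[atoms$element]
  atom_vol[is.na(atom_vol)] <- mean(av$volume)
  body_xyz <- rbind(xyz, grid)
  scattering_body(
    body_xyz,
    volume = c(atom_vol, rep(spacing^3, nrow(grid))),
    phase = c(rep("protein", nrow(xyz)), lab),
    contrast = c(protein = contrasts$delta_protein,
                 tails = contrasts$delta_tail,
                 heads = contrasts$delta_head),
    radius = spacing / 2, spacing = spacing)
}

#' Expand points by n-fold rotational symmetry about z
#'
#' Each point is replicated by rotations `2 pi k / n`, k = 0..n-1; points
#' on the axis (radial distance below `tol`) are kept once.
#'
#' @param xyz n x 3 matrix.
#' @param order symmetry order n >= 1.
#' @param tol axis tolerance (A).
#' @return expanded matrix with attribute `"source"` mapping rows to input
#'   rows.
#' @export
apply_symmetry <- function(xyz, order, tol = 1e-6) {
  xyz <- as.matrix(xyz)
  if (order < 1) stop("order must be >= 1")
  if (order == 1) { attr(xyz, "source") <- seq_len(nrow(xyz)); return(xyz) }
  axis <- sqrt(xyz[, 1]^2 + xyz[, 2]^2) < tol
  out <- list(); src <- list()
  for (k in 0:(order - 1)) {
    th <- 2 * pi * k / order
    rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    sel <- if (k == 0) rep(TRUE, nrow(xyz)) else !axis
    out[[k + 1]] <- xyz[sel, , drop = FALSE] %*% t(rot)
    src[[k + 1]] <- which(sel)
  }
  res <- do.call(rbind, out)
  attr(res, "source") <- unlist(src)
  res
}

phase_res_chain <- c(solvent = "SOL", protein = "PRO", particle = "PRO",
                     tails = "TAL", heads = "HED")

#' Write a bead model / body as a dummy-atom PDB file
#'
#' One dummy atom per point; the phase is encoded in the residue name
#' (SOL/PRO/TAL/HED) and chain ID, and the bead radius is recorded in a
#' REMARK header. Solvent beads are omitted by default.
#'
#' @param model a `bead_model` or [scattering_body()].
#' @param path destination.
#' @param keep_solvent include solvent beads.
#' @export
write_bead_pdb <- function(model, path, keep_solvent = FALSE) {
  xyz <- model$xyz
  phase <- as.character(model$phase)
  keep <- if (keep_solvent) rep(TRUE, length(phase)) else phase != "solvent"
  xyz <- xyz[keep, , drop = FALSE]
  phase <- phase[keep]
  resn <- phase_res_chain[phase]
  resn[is.na(resn)] <- "UNK"
  chain <- LETTERS[match(resn, unique(resn))]
  radius <- model$radius %||% model$r_bead %||% 0
  n <- nrow(xyz)
  lines <- c(
    sprintf("REMARK bead radius %.3f A", radius),
    sprintf("HETATM%5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            seq_len(n) %% 100000, resn, chain, (seq_len(n) - 1) %% 10000 + 1,
            xyz[, 1], xyz[, 2], xyz[, 3]),
    "END")
  writeLines(lines, path)
  invisible(path)
}
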