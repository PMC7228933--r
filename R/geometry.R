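#' Tanford length of an alkyl chain
#'
#' Empirical extended-chain length of a detergent tail with `n_c` carbons:
#' `l_c = 1.5 + 1.265 * n_c` Angstrom.
#'
#' @param n_c number of carbon atoms (>= 0).
#' @return length in Angstrom.
#' @export
tanford_length <- function(n_c) {
  if (any(n_c < 0)) stop("n_c must be non-negative")
  1.5 + 1.265 * n_c
}

#' Detergent specification
#'
#' Bundles the tail/head chemistry and derived lengths and volumes of a
#' solubilization detergent. The tail length is the Tanford length; the
#' head layer length defaults to the tail length (for common detergents the
#' head is at most as long as the tail). The tail volume uses the Tanford
#' volume formula `27.4 + 26.9 * n_c` A^3; the head volume comes from the
#' built-in table keyed by head formula, or an override, with an
#' electron-count based fallback (1.9 A^3 per electron, flagged).
#'
#' @param tail_formula,head_formula chemical formulae, e.g. `"C12H25"` and
#'   `"C12H21O11"` for a maltoside.
#' @param n_c carbon count of the tail; default counted from `tail_formula`.
#' @param head_volume optional head-group volume override (A^3).
#' @param head_length optional head layer length override (A).
#' @return object of class `detergent_spec`.
#' @export
detergent_spec <- function(tail_formula, head_formula, n_c = NULL,
                           head_volume = NULL, head_length = NULL) {
  tails <- parse_chemical_formula(tail_formula)
  heads <- parse_chemical_formula(head_formula)
  if (is.null(n_c)) {
    if (!"C" %in% names(tails)) stop("tail formula has no carbon")
    n_c <- tails[["C"]]
  }
  lt <- tanford_length(n_c)
  hv_flag <- FALSE
  if (is.null(head_volume)) {
    tab <- ms_table("detergent_heads")
    hit <- match(head_formula, tab$formula)
    if (!is.na(hit)) {
      head_volume <- tab$volume[hit]
    } else {
      head_volume <- 1.9 * electron_count(heads)
      hv_flag <- TRUE
    }
  }
  structure(list(
    n_c = as.integer(n_c), tail_formula = tails, head_formula = heads,
    tanford_tail = lt,
    head_length = head_length %||% lt,
    tail_volume = 27.4 + 26.9 * n_c,
    head_volume = head_volume,
    head_volume_estimated = hv_flag), class = "detergent_spec")
}

#' @export
print.detergent_spec <- function(x, ...) {
  cat(sprintf("detergent: C%d tail (Tanford %.2f A), head length %.2f A, head vol %.0f A^3\n",
              x$n_c, x$tanford_tail, x$head_length, x$head_volume))
  invisible(x)
}

#' Starting corona geometry for hybrid fitting
#'
#' For a spherical (ellipticity e = 1) detergent torus the starting
#' parameters are `a = b = t = Tanford_tail` with rotation 0; the
#' transmembrane thickness `a + t = 2 * Tanford_tail` is clamped at 45 A
#' (with a warning) since transmembrane thicknesses do not exceed that.
#'
#' @param spec a [detergent_spec()].
#' @return object of class `corona_geometry` with fields `a`, `b`, `e`,
#'   `t`, `rotation`, `transmembrane_thickness`, `warnings`.
#' @export
corona_start <- function(spec) {
  l <- spec$tanford_tail
  thick <- 2 * l
  warnings <- character(0)
  if (thick > 45) {
    thick <- 45
    warnings <- "THICKNESS_CLAMPED"
  }
  structure(list(a = l, b = l, e = 1, t = l, rotation = 0,
                 transmembrane_thickness = thick, warnings = warnings),
            class = "corona_geometry")
}

#' Transmembrane diameter from Dmax and the detergent lengths
#'
#' `D_memb = Dmax - 2 * Length(head) - 2 * Tanford(tail)`: the diameter of
#' the protein/solvent cylinder once the two detergent layers are removed
#' from the maximum dimension (measured orthogonal to the membrane normal).
#'
#' @param Dmax maximum particle dimension (A).
#' @param spec a [detergent_spec()].
#' @return D_memb in Angstrom.
#' @export
transmembrane_diameter <- function(Dmax, spec) {
  d <- Dmax - 2 * spec$head_length - 2 * spec$tanford_tail
  if (d <= 0)
    stop("Dmax too small for detergent corona (D_memb would be <= 0)")
  d
}

#' Closed-form torus volume and radius of gyration
#'
#' For a torus with central-path radius `R_major`, circular cross-section
#' radius `r_minor` and in-plane ellipticity `e` (coordinates scaled by `e`
#' along x and `1/e` along y): `V = 2 pi^2 R r^2` (independent of e) and
#' `Rg^2 = (e^2 + e^-2)(R^2 + 3/4 r^2)/2 + r^2/4` (so `Rg^2 = R^2 + r^2`
#' at e = 1). The hemi-torus (the upper or lower half, split at the
#' mid-plane) has half the volume and its own Rg about its own centroid.
#'
#' @param R_major central-path radius (A).
#' @param r_minor cross-section radius (A).
#' @param e ellipticity (dimensionless, default 1).
#' @return list with `volume`, `rg`, `hemi_volume`, `hemi_rg`, `hemi_zbar`.
#' @export
torus_metrics <- function(R_major, r_minor, e = 1) {
  if (R_major <= 0 || r_minor < 0 || e <= 0) stop("invalid torus parameters")
  V <- 2 * pi^2 * R_major * r_minor^2
  rho2 <- (e^2 + e^-2) * (R_major^2 + 0.75 * r_minor^2) / 2
  rg2 <- rho2 + r_minor^2 / 4
  zbar <- 4 * r_minor / (3 * pi)
  hemi_rg2 <- rho2 + r_minor^2 / 4 - zbar^2
  list(volume = V, rg = sqrt(rg2),
       hemi_volume = V / 2,
       hemi_rg = sqrt(max(hemi_rg2, 0)),
       hemi_zbar = zbar)
}

#' Volume and Rg of the confined corona regions
#'
#' The three-phase search grid confines the detergent tails to the solid of
#' revolution between the protein cylinder surface (radius `R_cyl`) and the
#' tail torus surface: points with `rho >= R_cyl` and
#' `(rho - R_cyl)^2 + z^2 <= r_out^2` (minus the part inside `r_in` for a
#' shell). Volumes are closed-form; Rg comes from deterministic 2D
#' quadrature over the cross-section.
#'
#' @param R_cyl cylinder (transmembrane) radius (A).
#' @param r_out outer cross-section radius (A).
#' @param r_in inner cross-section radius (A), 0 for the full tail body.
#' @return list with `volume` and `rg` (about the body centroid, which is
#'   at the origin by symmetry).
#' @export
corona_region_metrics <- function(R_cyl, r_out, r_in = 0) {
  stopifnot(R_cyl > 0, r_out > r_in, r_in >= 0)
  vol1 <- function(r) pi^2 * R_cyl * r^2 + (4 / 3) * pi * r^3
  V <- vol1(r_out) - vol1(r_in)
  # quadrature over u in [r_in, r_out], phi in [-pi/2, pi/2]
  nu <- 200; np <- 200
  u <- r_in + (r_out - r_in) * (seq_len(nu) - 0.5) / nu
  ph <- -pi / 2 + pi * (seq_len(np) - 0.5) / np
  du <- (r_out - r_in) / nu; dp <- pi / np
  U <- matrix(u, nu, np); P <- matrix(ph, nu, np, byrow = TRUE)
  rho <- R_cyl + U * cos(P)
  w <- rho * U * du * dp * 2 * pi
  m0 <- sum(w)
  rg <- sqrt(sum(w * (rho^2 + (U * sin(P))^2)) / m0)
  list(volume = V, rg = rg)
}

#' Electron densities and contrasts of the phases
#'
#' Derives the per-phase electron densities from the a priori record:
#' user-supplied densities take precedence; otherwise the tail density is
#' electrons(tail)/tail volume (Tanford volume formula), the head density is
#' electrons(head)/head volume, and the protein density comes from the
#' sequence through the residue electron/volume table (falling back to the
#' mean protein value 0.42 e-/A^3). Buffer defaults to water, 0.334 e-/A^3.
#' Contrasts are densities minus the buffer density. The typical maltoside/
#' water sign pattern (tail contrast < 0 < head contrast) is checked and
#' flagged, not enforced.
#'
#' @param apriori an [apriori_info()] record.
#' @param spec a [detergent_spec()].
#' @return object of class `contrast_set` with `rho_*`, `delta_*` and
#'   `flags`.
#' @export
phase_densities <- function(apriori, spec) {
  rho_buffer <- apriori$density_buffer %||% 0.334
  flags <- character(0)
  rho_tail <- apriori$density_tail %||% {
    if (is.null(spec$tail_formula)) stop("no density or formula for phase: tails")
    electron_count(spec$tail_formula) / spec$tail_volume
  }
  rho_head <- apriori$density_head %||% {
    if (is.null(spec$head_formula)) stop("no density or formula for phase: heads")
    if (isTRUE(spec$head_volume_estimated)) flags <- c(flags, "HEAD_VOLUME_ESTIMATED")
    electron_count(spec$head_formula) / spec$head_volume
  }
  rho_protein <- apriori$density_protein %||% {
    if (!is.null(apriori$sequence)) {
      sequence_composition(apriori$sequence)$density
    } else {
      flags <- c(flags, "PROTEIN_DENSITY_DEFAULT")
      0.42
    }
  }
  delta <- c(protein = rho_protein, tail = rho_tail, head = rho_head) - rho_buffer
  if (!(delta[["tail"]] < 0 && delta[["head"]] > 0))
    flags <- c(flags, "UNUSUAL_CONTRAST_SIGNS")
  structure(list(rho_protein = rho_protein, rho_tail = rho_tail,
                 rho_head = rho_head, rho_buffer = rho_buffer,
                 delta_protein = delta[["protein"]],
                 delta_tail = delta[["tail"]],
                 delta_head = delta[["head"]],
                 flags = flags), class = "contrast_set")
}

#' @export
print.contrast_set <- function(x, ...) {
  cat(sprintf("contrasts (e-/A^3): protein %+.3f, tails %+.3f, heads %+.3f (buffer %.3f)\n",
              x$delta_protein, x$delta_tail, x$delta_head, x$rho_buffer))
  invisible(x)
}

# hexagonal close-packed lattice filling a sphere of radius R, bead radius r
hcp_sphere <- function(R, r) {
  a <- 2 * r
  nmax <- ceiling(R / r) + 2
  k <- seq(-nmax, nmax)
  pts <- list()
  cz <- 2 * sqrt(6) / 3 * r
  cy <- sqrt(3) * r
  for (kk in k) {
    z <- cz * kk
    if (abs(z) > R + a) next
    for (jj in k) {
      y <- cy * (jj + (kk %% 2) / 3)
      if (abs(y) > R + a) next
      xs <- a * k + ((jj + kk) %% 2) * r
      keep <- xs^2 + y^2 + z^2 <= R^2
      if (any(keep))
        pts[[length(pts) + 1]] <- cbind(xs[keep], y, z)
    }
  }
  do.call(rbind, pts)
}

#' Classify grid points into corona search regions
#'
#' Region labels of the three-phase search volume: a protein/solvent
#' cylinder of radius `R_cyl` along z (the membrane normal), detergent
#' tails between the cylinder surface and the tail torus surface
#' (`u = hypot(rho - R_cyl, z) <= l_t`, split into upper and lower
#' hemi-tori by the membrane mid-plane), a head shell of thickness `l_h`
#' outside the tails, a fixed protein sphere of radius `r_fix` at the
#' origin, and boundary layers one bead diameter thick between adjacent
#' phases. Labels depend only on (rho, |z|), so every region maps onto
#' itself under any rotation about z.
#'
#' @param xyz n x 3 coordinates.
#' @param R_cyl cylinder radius (A), from [transmembrane_diameter()] / 2.
#' @param l_t,l_h tail and head lengths (A).
#' @param r_fix fixed protein sphere radius (A).
#' @param r_bead bead radius (A); boundary layers are one bead diameter.
#' @param Dmax sphere diameter (A).
#' @return character vector of labels: `fixed_protein_sphere`,
#'   `cylinder`, `tails`, `heads`, `boundary_12`, `boundary_23`,
#'   `boundary_solvent`, `solvent`, `outside`.
#' @export
classify_corona_region <- function(xyz, R_cyl, l_t, l_h, r_fix, r_bead, Dmax) {
  rho <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  z <- xyz[, 3]
  rr <- sqrt(rho^2 + z^2)
  u <- sqrt(pmax(rho - R_cyl, 0)^2 + z^2)
  lab <- rep("solvent", nrow(xyz))
  Rs <- (Dmax / 2) * (1 + 1e-9)   # tolerance keeps rotated surface beads in
  lab[rr > Rs] <- "outside"
  inside <- rr <= Rs
  corona_u_ok <- rho >= R_cyl - r_bead
  lab[inside & rho < R_cyl - r_bead] <- "cylinder"
  b12 <- inside & abs(rho - R_cyl) <= r_bead & abs(z) <= l_t
  tails <- inside & corona_u_ok & rho > R_cyl & u <= l_t - r_bead
  b23 <- inside & corona_u_ok & rho > R_cyl & abs(u - l_t) <= r_bead
  heads <- inside & corona_u_ok & rho > R_cyl & u > l_t + r_bead &
    u <= l_t + l_h - r_bead
  bsol <- inside & corona_u_ok & rho > R_cyl &
    abs(u - (l_t + l_h)) <= r_bead
  cyl_rest <- inside & rho >= R_cyl - r_bead & rho <= R_cyl & abs(z) > l_t
  lab[tails] <- "tails"
  lab[heads] <- "heads"
  lab[b23] <- "boundary_23"
  lab[bsol] <- "boundary_solvent"
  lab[b12] <- "boundary_12"
  lab[cyl_rest & lab == "solvent"] <- "cylinder"
  lab[inside & rr <= r_fix] <- "fixed_protein_sphere"
  lab
}

region_allowed_mask <- function(label) {
  # phase bits: 1 = solvent, 2 = protein, 4 = tails, 8 = heads
  switch(label,
         fixed_protein_sphere = 2L,
         cylinder = 1L + 2L,
         tails = 4L,
         heads = 8L,
         boundary_12 = 2L + 4L,
         boundary_23 = 4L + 8L,
         boundary_solvent = 1L + 8L,
         solvent = 1L,
         outside = 1L,
         stop("unknown region ", label))
}

#' Build the three-phase search volume
#'
#' Fills the Dmax sphere with a hexagonal close-packed bead lattice
#' (`beads_per_diameter` beads across the diameter) and assigns each bead a
#' region mask via [classify_corona_region()]. With `symmetry_order > 1`
#' the lattice is reduced to the asymmetric azimuthal wedge and replicated
#' by rotation about z, so symmetry-mate beads form orbits that the
#' annealer flips together.
#'
#' @param Dmax maximum particle dimension (A).
#' @param spec a [detergent_spec()].
#' @param beads_per_diameter grid resolution (default 40, >= 10).
#' @param symmetry_order n of the Pn point symmetry about z.
#' @param fixed_sphere_radius override of the fixed protein core radius;
#'   defaults to `max(3 bead diameters, half-volume radius from the
#'   sequence MW at 1.21 A^3/Da)` when `mw_da` is given.
#' @param mw_da optional protein molecular weight (Da) for the core radius.
#' @return object of class `search_volume`: `xyz`, `region`, `allowed`
#'   (bitmask), `fixed`, `orbit`, `r_bead`, `v_cell`, `D_memb`, geometry
#'   fields.
#' @export
build_search_volume <- function(Dmax, spec, beads_per_diameter = 40,
                                symmetry_order = 1,
                                fixed_sphere_radius = NULL, mw_da = NULL) {
  if (beads_per_diameter < 10)
    stop("grid too coarse to honor boundary layers (beads_per_diameter < 10)")
  D_memb <- transmembrane_diameter(Dmax, spec)
  R_cyl <- D_memb / 2
  l_t <- spec$tanford_tail; l_h <- spec$head_length
  r_bead <- Dmax / (2 * beads_per_diameter)
  if (is.null(fixed_sphere_radius)) {
    r50 <- if (!is.null(mw_da))
      (3 / (4 * pi) * 0.5 * mw_da * 1.21)^(1 / 3) else 0
    fixed_sphere_radius <- max(6 * r_bead, r50)
  }
  fixed_sphere_radius <- min(fixed_sphere_radius, R_cyl)
  xyz <- hcp_sphere(Dmax / 2, r_bead)
  n <- symmetry_order
  orbit <- seq_len(nrow(xyz))
  if (n > 1) {
    az <- atan2(xyz[, 2], xyz[, 1]) %% (2 * pi)
    rad <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
    keep <- az < 2 * pi / n | rad < 1e-6
    wedge <- xyz[keep, , drop = FALSE]
    axis <- sqrt(wedge[, 1]^2 + wedge[, 2]^2) < 1e-6
    reps <- list(); orb <- list()
    for (k in 0:(n - 1)) {
      th <- 2 * pi * k / n
      rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
      pts <- wedge %*% t(rot)
      sel <- if (k == 0) rep(TRUE, nrow(wedge)) else !axis
      reps[[k + 1]] <- pts[sel, , drop = FALSE]
      orb[[k + 1]] <- which(sel)
    }
    xyz <- do.call(rbind, reps)
    orbit <- unlist(orb)
  }
  region <- classify_corona_region(xyz, R_cyl, l_t, l_h,
                                   fixed_sphere_radius, r_bead, Dmax)
  keep <- region != "outside"
  xyz <- xyz[keep, , drop = FALSE]
  region <- region[keep]
  orbit <- orbit[keep]
  orbit <- match(orbit, sort(unique(orbit)))   # compact 1..norb
  allowed <- vapply(region, region_allowed_mask, integer(1))
  fixed <- region %in% c("fixed_protein_sphere", "solvent")
  structure(list(
    xyz = xyz, region = region, allowed = allowed, fixed = fixed,
    orbit = orbit, r_bead = r_bead,
    v_cell = (4 / 3) * pi * r_bead^3 / 0.7405,
    Dmax = Dmax, D_memb = D_memb, R_cyl = R_cyl,
    tanford_tail = l_t, head_length = l_h,
    fixed_sphere_radius = fixed_sphere_radius,
    symmetry_order = n, beads_per_diameter = beads_per_diameter),
    class = "search_volume")
}

#' @export
print.search_volume <- function(x, ...) {
  cat(sprintf("search_volume: %d beads (r = %.2f A), Dmax %.1f A, D_memb %.1f A, P%d\n",
              nrow(x$xyz), x$r_bead, x$Dmax, x$D_memb, x$symmetry_order))
  print(table(x$region))
  invisible(x)
}
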