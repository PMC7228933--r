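#' Phantom protein-detergent-complex specification
#'
#' Ground-truth description of a synthetic PDC used to exercise every stage
#' of the pipeline: a protein cylinder (radius, height), the confined
#' detergent corona (tail body between the cylinder surface and the tail
#' torus surface, head shell of the head-layer thickness around it --- the
#' same geometry family the three-phase search grid uses), per-phase
#' contrasts, the elution peak and the noise model
#' `sigma(s) = alpha * sqrt(I(s) + beta)`.
#'
#' @param protein_radius,protein_height protein cylinder dimensions (A).
#' @param n_c detergent tail carbons (tail length = Tanford length).
#' @param head_thickness head layer thickness (A); defaults to the tail
#'   length, matching the corona model's head = tail assumption.
#' @param delta_protein,delta_tail,delta_head phase contrasts (e-/A^3).
#' @param spacing phantom point spacing (A, <= 2 for a dense fill).
#' @param s_grid oracle curve grid (A^-1).
#' @param frames,peak_frame,peak_width,peak_amplitude elution series shape.
#' @param noise_alpha,noise_beta noise model parameters; `noise_alpha` is
#'   relative (scaled internally by sqrt(max I)).
#' @param seed RNG seed recorded in every output.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(protein_radius = 8, protein_height = 36, n_c = 8,
                         head_thickness = NULL,
                         delta_protein = 0.086, delta_tail = -0.057,
                         delta_head = 0.181, spacing = 2,
                         s_grid = seq(0.006, 0.25, length.out = 80),
                         frames = 1600, peak_frame = 800, peak_width = 30,
                         peak_amplitude = 1, noise_alpha = 0.01,
                         noise_beta = 0, seed = 1) {
  stopifnot(protein_radius > 0, protein_height > 0, n_c > 0, spacing > 0,
            frames > 0, peak_width > 0)
  structure(as.list(environment()), class = "phantom_spec")
}

#' Build a phantom PDC body and its oracle curve
#'
#' Fills the phantom bodies with a dense cubic lattice (protein cylinder,
#' tail body, head shell; overlaps resolved with priority protein > tails
#' > heads) and computes the oracle intensity by the exact unbinned Debye
#' sum. Ground-truth per-phase volumes (analytic and point-counted), Rg
#' values and Dmax are recorded alongside.
#'
#' @param spec a [phantom_spec()].
#' @return list with `body` ([scattering_body()]), `oracle`
#'   ([saxs_profile()] with the noise-model sigma attached), `truth`.
#' @export
make_phantom_pdc <- function(spec) {
  l_t <- tanford_length(spec$n_c)
  l_h <- spec$head_thickness %||% l_t
  R <- spec$protein_radius; H <- spec$protein_height
  ext <- R + l_t + l_h
  zext <- max(H / 2, l_t + l_h)
  h <- spec$spacing
  gx <- seq(-ext, ext, by = h)
  gz <- seq(-zext, zext, by = h)
  grid <- as.matrix(expand.grid(x = gx, y = gx, z = gz))
  rho <- sqrt(grid[, 1]^2 + grid[, 2]^2)
  z <- grid[, 3]
  u <- sqrt(pmax(rho - R, 0)^2 + z^2)
  in_prot <- rho <= R & abs(z) <= H / 2
  in_tail <- !in_prot & rho > R & u <= l_t
  in_head <- !in_prot & !in_tail & rho > R & u <= l_t + l_h
  sel <- in_prot | in_tail | in_head
  phase <- c("protein", "tails", "heads")[
    ifelse(in_prot[sel], 1L, ifelse(in_tail[sel], 2L, 3L))]
  body <- scattering_body(
    grid[sel, , drop = FALSE], volume = h^3, phase = phase,
    contrast = c(protein = spec$delta_protein, tails = spec$delta_tail,
                 heads = spec$delta_head),
    radius = h / 2, spacing = h)
  I <- debye_intensity(body, spec$s_grid, binned = FALSE)$intensity
  alpha <- spec$noise_alpha * sqrt(max(I))
  sigma <- alpha * sqrt(pmax(I, 0) + spec$noise_beta)
  sigma <- pmax(sigma, max(I) * 1e-9)
  oracle <- saxs_profile(spec$s_grid, I, sigma)
  tails_m <- corona_region_metrics(R, l_t)
  heads_m <- corona_region_metrics(R, l_t + l_h, l_t)
  counts <- table(factor(phase, c("protein", "tails", "heads")))
  truth <- list(
    seed = spec$seed, spec = spec,
    Dmax = 2 * max(sqrt(rho[sel]^2 + z[sel]^2)),
    volumes = c(protein = pi * R^2 * H, tails = tails_m$volume,
                heads = heads_m$volume),
    counted_volumes = as.numeric(counts) * h^3,
    rg = c(protein = sqrt(R^2 / 2 + H^2 / 12), tails = tails_m$rg,
           heads = heads_m$rg),
    tanford_tail = l_t, head_thickness = l_h)
  list(body = body, oracle = oracle, truth = truth)
}

#' Simulate a SEC-SAXS frame series with known ground truth
#'
#' Every frame is `buffer(s) + A * exp(-(l - l0)^2 / (2 w^2)) * I_pdc(s)`
#' plus zero-mean Gaussian noise with `sigma(s) = alpha sqrt(I + beta)`;
#' the recorded sigma column is the true noise level, so frame chi-squares
#' against the peak frame tend to one. The buffer curve is a smooth
#' decaying power law plus a constant. Ground-truth buffer and sample
#' frame ranges are returned alongside.
#'
#' @param pdc_curve the PDC excess scattering curve ([saxs_profile()] or
#'   list with `s`, `intensity`).
#' @param spec a [phantom_spec()] (elution peak, noise, seed fields).
#' @return list with `series` ([frame_series()]) and `truth` (0-based
#'   half-open `buffer_range`, `sample_range`, `peak_frame`, the buffer
#'   curve and the seed).
#' @export
simulate_frame_series <- function(pdc_curve, spec) {
  s <- pdc_curve$s
  Ip <- pdc_curve$intensity
  m <- spec$frames
  buffer <- 5 * max(Ip) * (1 + s / 0.05)^-2 + 0.05 * max(Ip)
  l <- seq_len(m)
  gain <- spec$peak_amplitude *
    exp(-(l - spec$peak_frame)^2 / (2 * spec$peak_width^2))
  # truncate below the detection floor so far-from-peak frames are pure buffer
  gain[gain < 1e-6 * spec$peak_amplitude] <- 0
  set.seed(spec$seed)
  Imat <- matrix(0, length(s), m)
  Smat <- matrix(0, length(s), m)
  alpha <- spec$noise_alpha * sqrt(max(buffer))
  for (j in l) {
    mu <- buffer + gain[j] * Ip
    sg <- pmax(alpha * sqrt(pmax(mu, 0) + spec$noise_beta),
               max(mu) * 1e-9)
    Imat[, j] <- mu + rnorm(length(s), 0, sg)
    Smat[, j] <- sg
  }
  w <- spec$peak_width
  half_w <- ceiling(w * sqrt(2 * log(2)))
  quiet <- which(gain == 0)
  first_run <- quiet[quiet < spec$peak_frame - 4 * w]
  truth <- list(
    buffer_range = c(0L, if (length(first_run)) max(first_run) else 0L),
    sample_range = c(spec$peak_frame - half_w - 1L,
                     spec$peak_frame + half_w),
    peak_frame = spec$peak_frame - 1L,
    buffer_curve = buffer, gain = gain, seed = spec$seed)
  list(series = frame_series(s, Imat, Smat), truth = truth)
}

#' Deterministic toy membrane protein: an ideal helical bundle
#'
#' Builds `n_helices` ideal poly-alanine alpha-helices (N, CA, C, O, CB
#' per residue; 1.5 A rise and 100 degrees per residue) standing on a
#' circle around the z axis, giving an exactly Cn-symmetric, centered,
#' z-aligned test protein that round-trips through PDB I/O.
#'
#' @param n_helices number of helices (>= 1).
#' @param length residues per helix.
#' @param bundle_radius circle radius (A); default grows with n.
#' @return an [atom_set()].
#' @export
make_toy_protein <- function(n_helices, length = 20, bundle_radius = NULL) {
  if (n_helices < 1) stop("n_helices must be >= 1")
  if (is.null(bundle_radius))
    bundle_radius <- if (n_helices == 1) 0 else max(6, 5 / sin(pi / n_helices) / 2)
  rise <- 1.5; twist <- 100 * pi / 180
  i <- seq_len(length)
  th <- (i - 1) * twist
  zz <- (i - 1) * rise
  # offsets (radius from helix axis, angular lead, z shift) per atom type
  offs <- list(N = c(1.6, -0.6, -0.9), CA = c(2.3, 0, 0),
               C = c(1.7, 0.6, 0.8), O = c(2.0, 0.9, 1.9),
               CB = c(3.4, -0.3, -0.2))
  one_helix <- function(cx, cy, phase0) {
    # residue-major order: N, CA, C, O, CB per residue
    xyz <- do.call(rbind, lapply(i, function(res) {
      t(vapply(offs, function(o)
        c(cx + o[1] * cos(th[res] + phase0 + o[2]),
          cy + o[1] * sin(th[res] + phase0 + o[2]),
          zz[res] + o[3]), numeric(3)))
    }))
    list(xyz = xyz, name = rep(names(offs), length),
         resno = rep(i, each = 5))
  }
  # build helix 0, then rotate copies for exact Cn symmetry
  h0 <- one_helix(bundle_radius, 0, 0)
  xyz_all <- list(h0$xyz)
  if (n_helices > 1) {
    for (k in seq_len(n_helices - 1)) {
      a <- 2 * pi * k / n_helices
      rot <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
      xyz_all[[k + 1]] <- h0$xyz %*% t(rot)
    }
  }
  xyz <- do.call(rbind, xyz_all)
  xyz[, 3] <- xyz[, 3] - mean(range(xyz[, 3]))
  n_at <- nrow(xyz)
  element <- substr(rep(h0$name, n_helices), 1, 1)
  atoms <- atom_set(xyz, element,
                    resid = rep("ALA", n_at),
                    resno = rep(h0$resno, n_helices) +
                      rep((seq_len(n_helices) - 1) * length, each = 5 * length),
                    chain = rep(LETTERS[seq_len(n_helices)], each = 5 * length))
  attr(atoms, "atom_names") <- rep(h0$name, n_helices)
  atoms
}

#' Closed-form scattering of a homogeneous sphere
#'
#' `I(s) = I0 [3 (sin u - u cos u)/u^3]^2` with `u = sR`; the standard
#' oracle for Guinier, P(r) and Porod checks (`Rg = sqrt(3/5) R`,
#' `Dmax = 2R`, `V = 4/3 pi R^3`).
#'
#' @param s grid (A^-1).
#' @param R sphere radius (A).
#' @param I0 forward intensity.
#' @param rel_sigma relative uncertainty attached to the profile.
#' @return a [saxs_profile()].
#' @export
sphere_curve <- function(s, R, I0 = 1, rel_sigma = 0.01) {
  u <- s * R
  amp <- ifelse(abs(u) < 1e-8, 1, 3 * (sin(u) - u * cos(u)) / u^3)
  I <- I0 * amp^2
  saxs_profile(s, I, pmax(rel_sigma * I, rel_sigma * I0 * 1e-6))
}
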