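#' Annealing configuration
#'
#' Tunables of the simulated-annealing engines. The starting temperature is
#' auto-calibrated (median |dE| of sampled moves, about 50% initial
#' acceptance) when `t0 < 0`; `t0 = 0` runs a greedy descent. Penalty
#' weights multiply the discontinuity (fraction of non-solvent beads with
#' fewer than 3 like-phase contacts), looseness (1 - largest connected
#' component fraction, averaged over phases), and squared relative
#' deviations of per-phase volume and Rg from their expectations.
#'
#' @param seed RNG seed used for the whole run (reproducible bit-for-bit).
#' @param t0 starting temperature (<0 = auto, 0 = greedy).
#' @param cool multiplicative cooling per sweep.
#' @param sweeps_min,sweeps_max,stall schedule bounds: at least
#'   `sweeps_min` sweeps, stop after `stall` sweeps without improvement,
#'   never more than `sweeps_max`.
#' @param w_disc,w_loose,w_vol,w_rg penalty weights.
#' @param loose_every refresh the looseness term after this many accepted
#'   moves (lagged evaluation); 0 evaluates it exactly at every trial
#'   (small grids only).
#' @param fit_const include an additive constant in the chi-square scale
#'   fit.
#' @param max_points thin the data to at most this many s points.
#' @return list of class `anneal_config`.
#' @export
anneal_config <- function(seed = 42, t0 = -1, cool = 0.97,
                          sweeps_min = 40, sweeps_max = 150, stall = 12,
                          w_disc = 1, w_loose = 1, w_vol = 20, w_rg = 10,
                          loose_every = 500, fit_const = FALSE,
                          max_points = 80) {
  stopifnot(cool > 0, cool < 1, w_disc >= 0, w_loose >= 0,
            w_vol >= 0, w_rg >= 0)
  structure(as.list(environment()), class = "anneal_config")
}

thin_profile <- function(profile, max_points) {
  n <- length(profile$s)
  if (n <= max_points) return(profile)
  profile_subset(profile, unique(round(seq(1, n, length.out = max_points))))
}

orbit_csr <- function(orbit) {
  ord <- order(orbit)
  ptr <- c(0L, cumsum(tabulate(orbit)))
  list(ptr = as.integer(ptr), idx = as.integer(ord - 1L))
}

phase_levels <- c("solvent", "protein", "tails", "heads")

run_annealer <- function(xyz, phase0, allowed, fixed, contrast, r_bead,
                         v_cell, profile, vol_target, rg_target, orbit,
                         config, engine, exact_loose = FALSE) {
  nb <- neighbors_within_cpp(xyz, 2.1 * r_bead)
  oc <- orbit_csr(orbit)
  bw <- min(pi / (8 * max(profile$s)), r_bead)
  use_dmat <- nrow(xyz) <= 12000
  set.seed(config$seed)
  res <- anneal_cpp(xyz, as.integer(phase0), as.integer(allowed),
                    as.logical(fixed), as.numeric(contrast),
                    r_bead, v_cell,
                    profile$s, profile$intensity, profile$sigma,
                    as.numeric(vol_target), as.numeric(rg_target),
                    config$w_vol, config$w_rg, config$w_disc, config$w_loose,
                    nb$ptr, nb$idx, oc$ptr, oc$idx,
                    bw, config$t0, config$cool,
                    config$sweeps_min, config$sweeps_max, config$stall,
                    config$loose_every, config$fit_const, use_dmat,
                    exact_loose)
  structure(list(
    xyz = xyz, radius = r_bead, v_cell = v_cell,
    phase = factor(phase_levels[res$phase + 1L],
                   levels = phase_levels[seq_len(length(contrast) + 1L)]),
    phase_index = res$phase,
    contrast = contrast,
    chi2 = res$chi2, energy = res$energy, scale = res$scale,
    constant = res$constant,
    penalties = list(discontinuity = res$discontinuity,
                     looseness = res$looseness,
                     volume = res$vol_penalty, rg = res$rg_penalty),
    I_model = res$I_model, s_fit = profile$s,
    energy_trace = res$energy_trace,
    provenance = list(engine = engine, seed = config$seed,
                      sweeps = res$sweeps, trials = res$trials,
                      accepted = res$accepted, config = config)),
    class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("bead_model [%s]: %d beads, chi2 = %.3f, energy = %.3f (seed %d, %d sweeps)\n",
              x$provenance$engine, nrow(x$xyz), x$chi2, x$energy,
              x$provenance$seed, x$provenance$sweeps))
  print(table(x$phase))
  invisible(x)
}

model_points <- function(model) {
  if (inherits(model, "bead_model"))
    model$xyz[model$phase != "solvent", , drop = FALSE]
  else if (inherits(model, "scattering_body")) model$xyz
  else as.matrix(model)
}

#' Hybrid detergent-corona fit around an atomic model
#'
#' Grid search of the corona geometry `(a, b, t)` in the range start
#' +/- Tanford_tail/3 around the [corona_start()] values, with ellipticity
#' and rotation fixed (e = 1, rotation = 0). Each node fills the corona
#' ([fill_corona()]), computes the Debye intensity, fits scale (and an
#' optional constant) by weighted least squares and records chi-square;
#' nodes violating the 45 A transmembrane thickness cap (a + t) are
#' skipped. A fit with chi-square above 2 carries the poor-fit warning.
#'
#' @param atoms an [atom_set()]; aligned internally unless `align = FALSE`.
#' @param profile the subtracted [saxs_profile()].
#' @param spec a [detergent_spec()].
#' @param contrasts a [phase_densities()] contrast set.
#' @param n_steps grid nodes per axis (default 7, i.e. step Tanford/6).
#' @param spacing corona lattice spacing (A).
#' @param fit_const fit an additive constant.
#' @param align align atoms to principal axes first.
#' @param max_points thin the data to this many points for the search.
#' @return object of class `corona_fit`: `geometry` (best a, b, t, e,
#'   rotation), `chi2`, `scale`, `constant`, `grid` (data.frame of all
#'   evaluated nodes), `warnings`, `I_model`, `body`.
#' @export
fit_corona <- function(atoms, profile, spec, contrasts, n_steps = 7,
                       spacing = 3, fit_const = TRUE, align = TRUE,
                       max_points = 80) {
  if (align) atoms <- align_principal_axes(atoms)
  start <- corona_start(spec)
  l <- spec$tanford_tail
  offs <- seq(-l / 3, l / 3, length.out = n_steps)
  prof <- thin_profile(profile, max_points)
  w <- 1 / prof$sigma^2
  eval_node <- function(a, b, t) {
    body <- fill_corona(atoms, list(a = a, b = b, e = 1, t = t), contrasts,
                        spacing = spacing)
    Im <- debye_intensity(body, prof$s)$intensity
    if (fit_const) {
      X <- cbind(Im, 1)
      cf <- solve(crossprod(X * sqrt(w)), crossprod(X * w, prof$intensity))
      pred <- drop(X %*% cf)
      sc <- cf[1]; b0 <- cf[2]
    } else {
      sc <- sum(w * Im * prof$intensity) / sum(w * Im^2)
      pred <- sc * Im; b0 <- 0
    }
    chi2 <- sum(w * (prof$intensity - pred)^2) / (length(prof$s) - 1)
    list(chi2 = chi2, scale = sc, constant = b0, body = body, I_model = pred)
  }
  grid <- expand.grid(a = start$a + offs, b = start$b + offs,
                      t = start$t + offs)
  grid <- grid[grid$a + grid$t <= 45 & grid$a > 0 & grid$b > 0 & grid$t > 0, ]
  if (nrow(grid) == 0) stop("degenerate corona search domain")
  grid$chi2 <- NA_real_
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    nd <- tryCatch(eval_node(grid$a[i], grid$b[i], grid$t[i]),
                   error = function(e) NULL)
    if (is.null(nd)) next
    grid$chi2[i] <- nd$chi2
    if (is.null(best) || nd$chi2 < best$chi2)
      best <- c(nd, list(a = grid$a[i], b = grid$b[i], t = grid$t[i]))
  }
  if (is.null(best)) stop("corona fit failed at every grid node")
  warnings <- character(0)
  if (best$chi2 > 2) warnings <- "FIT_POOR_CHI2"
  structure(list(
    geometry = list(a = best$a, b = best$b, t = best$t, e = 1, rotation = 0,
                    transmembrane_thickness = best$a + best$t),
    chi2 = best$chi2, scale = best$scale, constant = best$constant,
    grid = grid, warnings = warnings,
    I_model = best$I_model, s_fit = prof$s, body = best$body,
    atoms = atoms), class = "corona_fit")
}

#' @export
print.corona_fit <- function(x, ...) {
  cat(sprintf("corona_fit: a = %.2f, b = %.2f, t = %.2f A (e = 1), chi2 = %.3f%s\n",
              x$geometry$a, x$geometry$b, x$geometry$t, x$chi2,
              if (length(x$warnings)) paste0(" [", x$warnings, "]") else ""))
  invisible(x)
}

#' Three-phase constrained ab initio bead modeling
#'
#' Simulated annealing of per-bead phase assignments (solvent, protein,
#' detergent tails, detergent heads) on the confined search grid from
#' [build_search_volume()], against the subtracted curve. Beads only take
#' phases allowed by their region mask (boundary layers may take either
#' adjacent phase); the fixed protein core never flips. The energy adds
#' discontinuity and looseness penalties and per-phase volume and Rg
#' restraints to the chi-square.
#'
#' @param volume a [build_search_volume()] grid.
#' @param profile the subtracted [saxs_profile()].
#' @param contrasts a [phase_densities()] contrast set.
#' @param expected list with numeric vectors `volumes` and `rg`, each with
#'   entries `protein`, `tails`, `heads` (NA to skip a restraint); see
#'   [expected_phase_metrics()].
#' @param config an [anneal_config()].
#' @return a `bead_model`.
#' @export
anneal_multiphase <- function(volume, profile, contrasts, expected,
                              config = anneal_config()) {
  prof <- thin_profile(profile, config$max_points)
  contrast <- c(protein = contrasts$delta_protein,
                tails = contrasts$delta_tail,
                heads = contrasts$delta_head)
  # initial state: region cores at their nominal phase, cylinder solvent
  ph0 <- integer(nrow(volume$xyz))
  ph0[volume$region %in% c("fixed_protein_sphere")] <- 1L
  ph0[volume$region %in% c("tails", "boundary_12", "boundary_23")] <- 2L
  ph0[volume$region %in% c("heads", "boundary_solvent")] <- 3L
  need <- c("protein", "tails", "heads")
  can <- vapply(1:3, function(p) any(bitwAnd(volume$allowed, bitwShiftL(1L, p)) > 0),
                logical(1))
  if (!all(can))
    stop("no beads assignable to required phase: ", need[!can][1])
  vt <- expected$volumes[need]
  rt <- expected$rg[need]
  model <- run_annealer(volume$xyz, ph0, volume$allowed, volume$fixed,
                        contrast, volume$r_bead, volume$v_cell, prof,
                        vt, rt, volume$orbit, config,
                        engine = "multiphase",
                        exact_loose = nrow(volume$xyz) <= 4000 &&
                          config$loose_every == 0)
  model$region <- volume$region
  model$search_volume <- volume
  model
}

#' Expected per-phase volumes and Rg from geometry
#'
#' Tail and head expectations come from the confined-corona closed forms
#' ([corona_region_metrics()]); the protein expectation is the Porod
#' volume minus the corona (floored at 10% of V_Porod), its Rg left free.
#'
#' @param volume a [build_search_volume()] grid.
#' @param v_porod experimental Porod volume (A^3), NA to skip.
#' @return list with `volumes` and `rg` named vectors.
#' @export
expected_phase_metrics <- function(volume, v_porod = NA) {
  tails <- corona_region_metrics(volume$R_cyl, volume$tanford_tail)
  heads <- corona_region_metrics(volume$R_cyl,
                                 volume$tanford_tail + volume$head_length,
                                 volume$tanford_tail)
  vp <- if (is.finite(v_porod))
    max(v_porod - tails$volume - heads$volume, 0.1 * v_porod) else NA
  list(volumes = c(protein = vp, tails = tails$volume, heads = heads$volume),
       rg = c(protein = NA, tails = tails$rg, heads = heads$rg))
}

#' Single-phase ab initio shape reconstruction
#'
#' One-phase (particle vs solvent) annealing in a spherical search volume
#' of diameter Dmax against the low-s part of the curve (`s <= s_max`),
#' with Pn symmetry imposed through the asymmetric-wedge scheme (symmetry
#' mates flip together, so the output is exactly n-fold symmetric).
#'
#' @param profile the subtracted [saxs_profile()].
#' @param s_max fit range limit (A^-1), e.g. from [first_minimum_smax()].
#' @param Dmax search sphere diameter (A), e.g. from [pr_transform()].
#' @param symmetry_order Pn order about z.
#' @param config an [anneal_config()].
#' @param beads_per_diameter grid resolution.
#' @param v_porod,rg optional volume/Rg restraints for the particle phase.
#' @param allowed optional per-bead allowed-phase bitmask override (used by
#'   the consensus refinement to lock beads outside the average volume).
#' @param grid optional pre-built grid (list with xyz, orbit, r_bead,
#'   v_cell) to reuse between runs.
#' @return a `bead_model` with phases `solvent`/`particle`.
#' @export
anneal_singlephase <- function(profile, s_max, Dmax, symmetry_order = 1,
                               config = anneal_config(),
                               beads_per_diameter = 24,
                               v_porod = NA, rg = NA,
                               allowed = NULL, grid = NULL) {
  keep <- profile$s <= s_max
  if (sum(keep) < 5) stop("insufficient data range: s_max below the 5th data point")
  prof <- thin_profile(profile_subset(profile, keep), config$max_points)
  if (is.null(grid)) grid <- singlephase_grid(Dmax, beads_per_diameter,
                                              symmetry_order)
  n <- nrow(grid$xyz)
  if (is.null(allowed)) allowed <- rep(3L, n)      # solvent | particle
  set.seed(config$seed)
  ph0 <- ifelse(bitwAnd(allowed, 2L) > 0 &
                  runif(n)[grid$orbit] < 0.4, 1L, 0L)
  ph0[bitwAnd(allowed, 2L) == 0] <- 0L
  model <- run_annealer(grid$xyz, ph0, allowed, rep(FALSE, n),
                        c(particle = 1), grid$r_bead, grid$v_cell, prof,
                        v_porod, rg, grid$orbit, config,
                        engine = "singlephase",
                        exact_loose = n <= 4000 && config$loose_every == 0)
  model$phase <- factor(c("solvent", "particle")[model$phase_index + 1L],
                        levels = c("solvent", "particle"))
  model$symmetry_order <- symmetry_order
  model$grid <- grid
  model
}

#' Spherical bead grid for single-phase modeling
#' @param Dmax sphere diameter (A).
#' @param beads_per_diameter resolution.
#' @param symmetry_order Pn order (wedge + replication when > 1).
#' @return list with `xyz`, `orbit`, `r_bead`, `v_cell`.
#' @export
singlephase_grid <- function(Dmax, beads_per_diameter = 24, symmetry_order = 1) {
  r_bead <- Dmax / (2 * beads_per_diameter)
  xyz <- hcp_sphere(Dmax / 2, r_bead)
  orbit <- seq_len(nrow(xyz))
  if (symmetry_order > 1) {
    az <- atan2(xyz[, 2], xyz[, 1]) %% (2 * pi)
    rad <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
    keep <- az < 2 * pi / symmetry_order | rad < 1e-6
    wedge <- xyz[keep, , drop = FALSE]
    xyz <- apply_symmetry(wedge, symmetry_order)
    orbit <- attr(xyz, "source")
  }
  list(xyz = xyz, orbit = as.integer(orbit), r_bead = r_bead,
       v_cell = (4 / 3) * pi * r_bead^3 / 0.7405)
}

#' Normalized spatial discrepancy between two models
#'
#' Kozin-Svergun NSD: the symmetrized mean of squared nearest-neighbour
#' distances between the two point sets, each term normalized by the other
#' set's mean nearest-neighbour spacing; 0 for identical sets, around 1
#' for similar models.
#'
#' @param model_a,model_b `bead_model`s, bodies or n x 3 matrices
#'   (solvent beads are dropped from bead models).
#' @return dimensionless NSD.
#' @export
nsd <- function(model_a, model_b) {
  A <- model_points(model_a); B <- model_points(model_b)
  if (nrow(A) < 2 || nrow(B) < 2)
    stop("NSD needs at least 2 points per model")
  nsd_cpp(A, B)
}

rotation_candidates <- function() {
  flips <- expand.grid(c(1, -1), c(1, -1), c(1, -1))
  lapply(seq_len(nrow(flips)), function(i) diag(as.numeric(flips[i, ])))
}

#' Align a model to a reference (principal axes + enantiomer check)
#'
#' Both point sets are centered and rotated to principal axes; the 8
#' axis-sign combinations (including improper ones, i.e. the mirror image)
#' are tried and the one with the lowest NSD to the reference is kept.
#'
#' @param model points or `bead_model` to align.
#' @param ref reference points or `bead_model`.
#' @return aligned n x 3 matrix of the model's occupied points.
#' @export
align_to_reference <- function(model, ref) {
  A <- model_points(ref); B <- model_points(model)
  pax <- function(X) {
    ctr <- colMeans(X)
    X0 <- sweep(X, 2, ctr)
    ev <- tryCatch(eigen(crossprod(X0) / nrow(X0), symmetric = TRUE),
                   error = function(e) NULL)
    if (is.null(ev) || any(!is.finite(ev$values))) return(NULL)
    X0 %*% ev$vectors
  }
  Ap <- pax(A); Bp <- pax(B)
  if (is.null(Ap) || is.null(Bp)) {
    warning("degenerate inertia tensor; identity alignment used")
    return(B)
  }
  best <- NULL; bestv <- Inf
  for (Fm in rotation_candidates()) {
    cand <- Bp %*% Fm
    v <- nsd_cpp(Ap, cand)
    if (v < bestv) { bestv <- v; best <- cand }
  }
  # return in the reference's original frame
  ctrA <- colMeans(A)
  evA <- eigen(crossprod(sweep(A, 2, ctrA)) / nrow(A), symmetric = TRUE)
  sweep(best %*% t(evA$vectors), 2, ctrA, `+`)
}

#' Consensus model from independent ab initio runs
#'
#' From an ensemble of independent reconstructions: computes all pairwise
#' NSDs, takes as reference the model with the lowest mean NSD to the
#' others, aligns every model to it (principal axes with enantiomer
#' check), thresholds the bead occupancy map to an averaged volume, and
#' runs one refinement annealing seeded from that volume with beads
#' outside it locked to solvent. The pairwise NSD mean/sd are recorded in
#' the result's provenance.
#'
#' @param models list of >= 2 single-phase `bead_model`s on one grid.
#' @param profile the subtracted [saxs_profile()].
#' @param s_max fit range for the refinement.
#' @param config an [anneal_config()] for the refinement run.
#' @param occupancy_threshold fraction of models that must cover a bead
#'   for it to enter the averaged volume.
#' @return refined `bead_model`; provenance carries `nsd_mean`, `nsd_sd`,
#'   `nsd_matrix`, `reference`.
#' @export
consensus_model <- function(models, profile, s_max,
                            config = anneal_config(),
                            occupancy_threshold = 0.5) {
  m <- length(models)
  if (m < 2) stop("need at least 2 models")
  D <- matrix(0, m, m)
  for (i in 1:(m - 1)) for (j in (i + 1):m)
    D[i, j] <- D[j, i] <- nsd(models[[i]], models[[j]])
  mean_nsd <- rowSums(D) / (m - 1)
  ref_i <- which.min(mean_nsd)
  ref <- models[[ref_i]]
  grid <- ref$grid
  occ <- numeric(nrow(grid$xyz))
  for (j in seq_len(m)) {
    pts <- if (j == ref_i) model_points(ref) else
      align_to_reference(models[[j]], ref)
    hit <- points_near_cpp(grid$xyz, pts, 1.5 * grid$r_bead)
    occ <- occ + as.numeric(hit)
  }
  inside <- occ >= occupancy_threshold * m
  allowed <- ifelse(inside, 3L, 1L)
  refined <- anneal_singlephase(profile, s_max, NA, ref$symmetry_order %||% 1,
                                config = config, allowed = allowed,
                                grid = grid)
  up <- D[upper.tri(D)]
  refined$provenance$nsd_mean <- mean(up)
  refined$provenance$nsd_sd <- if (length(up) > 1) sd(up) else 0
  refined$provenance$nsd_matrix <- D
  refined$provenance$reference <- ref_i
  refined$provenance$averaged_volume_beads <- sum(inside)
  refined
}
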