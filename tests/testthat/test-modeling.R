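test_that("corona fit recovers a known on-grid geometry", {
  toy <- make_toy_protein(3, 20)
  spec <- detergent_spec("C8H17", "C6H11O6")
  ap <- apriori_info(head_formula = "C6H11O6", tail_formula = "C8H17")
  ctr <- phase_densities(ap, spec)
  start <- corona_start(spec)
  l <- spec$tanford_tail
  offs <- seq(-l / 3, l / 3, length.out = 7)
  true_geom <- list(a = start$a + offs[5], b = start$b + offs[3],
                    t = start$t + offs[4], e = 1)
  tb <- fill_corona(toy, true_geom, ctr, spacing = 4)
  s <- seq(0.008, 0.25, length.out = 80)
  I <- debye_intensity(tb, s)$intensity
  prof <- saxs_profile(s, I, pmax(0.02 * abs(I), 1e-8 * max(I)))
  fit <- fit_corona(toy, prof, spec, ctr, spacing = 4, align = FALSE)
  expect_equal(fit$geometry$a, true_geom$a, tolerance = 1e-9)
  expect_equal(fit$geometry$b, true_geom$b, tolerance = 1e-9)
  expect_equal(fit$geometry$t, true_geom$t, tolerance = 1e-9)
  expect_lt(fit$chi2, 0.5)
  # reported minimum is <= every evaluated grid node
  expect_true(all(fit$chi2 <= fit$grid$chi2 + 1e-12, na.rm = TRUE))
  expect_equal(nrow(fit$grid), sum(fit$grid$a + fit$grid$t <= 45))
})

test_that("corona search domain honors the 45 A thickness cap", {
  spec22 <- detergent_spec("C22H45", "C12H21O11")   # 2l = 61.2 > 45
  toy <- make_toy_protein(3, 20)
  ap <- apriori_info(head_formula = "C12H21O11", tail_formula = "C22H45")
  ctr <- phase_densities(ap, spec22)
  s <- seq(0.008, 0.2, length.out = 50)
  # evaluate the domain only (3 nodes/axis keeps this quick)
  I <- debye_intensity(fill_corona(toy, corona_start(spec22), ctr, spacing = 5),
                       s)$intensity
  prof <- saxs_profile(s, I, 0.02 * abs(I) + 1e-8 * max(I))
  fit <- fit_corona(toy, prof, spec22, ctr, n_steps = 3, spacing = 5,
                    align = FALSE)
  expect_true(all(fit$grid$a + fit$grid$t <= 45))
  expect_lte(fit$geometry$a + fit$geometry$t, 45)
})

test_that("three-phase annealer respects masks and basic engine properties", {
  ph <- small_phantom()
  spec <- detergent_spec("C8H17", "C6H11O6")
  vol <- build_search_volume(ph$truth$Dmax, spec, beads_per_diameter = 16)
  ctr <- phase_densities(apriori_info(head_formula = "C6H11O6",
                                      tail_formula = "C8H17"), spec)
  ctr$delta_protein <- 0.086; ctr$delta_tail <- -0.057; ctr$delta_head <- 0.181
  expd <- list(volumes = ph$truth$volumes, rg = ph$truth$rg)

  # zero iterations: initial configuration returned unchanged
  m0 <- anneal_multiphase(vol, ph$oracle, ctr, expd,
                          anneal_config(seed = 1, sweeps_max = 0))
  init <- integer(nrow(vol$xyz))
  init[vol$region == "fixed_protein_sphere"] <- 1L
  init[vol$region %in% c("tails", "boundary_12", "boundary_23")] <- 2L
  init[vol$region %in% c("heads", "boundary_solvent")] <- 3L
  expect_equal(m0$phase_index, init)

  cfg <- quick_anneal_config(seed = 3)
  m <- anneal_multiphase(vol, ph$oracle, ctr, expd, cfg)
  # masks are never violated
  ph_idx <- m$phase_index
  for (i in seq_along(ph_idx))
    expect_true(bitwAnd(vol$allowed[i], bitwShiftL(1L, ph_idx[i])) > 0)
  expect_true(all(ph_idx[vol$region == "fixed_protein_sphere"] == 1L))
  # tails confined to the masked region
  tz <- abs(m$xyz[m$phase == "tails", 3])
  expect_true(all(tz <= vol$tanford_tail + vol$r_bead + 1e-9))

  # determinism: same seed, same inputs -> bit-identical assignment
  m2 <- anneal_multiphase(vol, ph$oracle, ctr, expd, cfg)
  expect_identical(m$phase_index, m2$phase_index)
  expect_identical(m$chi2, m2$chi2)
})

test_that("greedy descent never increases the energy", {
  s <- seq(0.01, 0.15, length.out = 60)
  sp <- sphere_curve(s, 20, I0 = 1e5, rel_sigma = 0.02)
  cfg <- anneal_config(seed = 2, t0 = 0, cool = 0.97, sweeps_min = 10,
                       sweeps_max = 25, stall = 30, w_loose = 0)
  m <- anneal_singlephase(sp, 0.15, 44, config = cfg, beads_per_diameter = 10,
                          v_porod = 4 / 3 * pi * 20^3)
  expect_true(all(diff(m$energy_trace) <= 1e-8))
})

test_that("single-phase reconstruction recovers size and symmetry", {
  s <- seq(0.006, 0.2, length.out = 120)
  sp <- sphere_curve(s, 30, I0 = 1e6, rel_sigma = 0.02)
  m <- anneal_singlephase(sp, 0.15, 66, config = quick_anneal_config(seed = 5),
                          beads_per_diameter = 16, v_porod = 4 / 3 * pi * 30^3)
  pts <- m$xyz[m$phase != "solvent", ]
  rg <- sqrt(mean(rowSums(scale(pts, scale = FALSE)^2)))
  expect_lt(abs(rg - sqrt(3 / 5) * 30) / (sqrt(3 / 5) * 30), 0.05)

  # insufficient range errors
  expect_error(anneal_singlephase(sp, 0.007, 66), "insufficient data range")

  # C4 ground truth: output exactly C4 symmetric by construction
  m4 <- anneal_singlephase(sp, 0.15, 66, symmetry_order = 4,
                           config = quick_anneal_config(seed = 6),
                           beads_per_diameter = 12)
  occ <- m4$xyz[m4$phase != "solvent", ]
  rot <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  r4 <- occ %*% t(rot)
  mismatch <- max(vapply(seq_len(nrow(occ)), function(i)
    min(sqrt(rowSums(sweep(occ, 2, r4[i, ])^2))), numeric(1)))
  expect_lt(mismatch, 1e-9)
})

test_that("hollow shells reconstruct hollow", {
  sh <- shell_curve(seq(0.006, 0.25, length.out = 150), 20, 30)
  m <- anneal_singlephase(sh, 0.2, 66,
                          config = anneal_config(seed = 3, sweeps_min = 40,
                                                 sweeps_max = 100, stall = 12),
                          beads_per_diameter = 16)
  expect_lt(hollowness(m), 0.3)
})

test_that("NSD is a symmetric discrepancy agreeing with the brute oracle", {
  set.seed(2)
  A <- matrix(rnorm(300), ncol = 3)
  B <- matrix(rnorm(330), ncol = 3)
  expect_equal(nsd(A, A), 0)
  expect_equal(nsd(A, B), nsd(B, A))
  expect_equal(nsd(A, B), nsd_oracle_r(A, B), tolerance = 1e-12)
  expect_error(nsd(matrix(0, 1, 3), A), "at least 2")
})

test_that("consensus picks a central reference and averages the ensemble", {
  s <- seq(0.006, 0.18, length.out = 100)
  sp <- sphere_curve(s, 30, I0 = 1e6, rel_sigma = 0.02)
  runs <- lapply(1:5, function(k)
    anneal_singlephase(sp, 0.15, 66, config = quick_anneal_config(seed = 100 + k),
                       beads_per_diameter = 12, v_porod = 4 / 3 * pi * 30^3))
  cons <- consensus_model(runs, sp, 0.15, config = quick_anneal_config(seed = 99))
  expect_true(is.finite(cons$provenance$nsd_mean))
  expect_gt(cons$provenance$averaged_volume_beads, 0)
  pts <- cons$xyz[cons$phase != "solvent", ]
  rg <- sqrt(mean(rowSums(scale(pts, scale = FALSE)^2)))
  expect_lt(abs(rg - sqrt(3 / 5) * 30) / (sqrt(3 / 5) * 30), 0.08)

  # identical copies: reference is that model, all NSDs 0
  copies <- rep(runs[1], 4)
  cons2 <- consensus_model(copies, sp, 0.15,
                           config = anneal_config(seed = 98, sweeps_max = 0))
  expect_equal(cons2$provenance$nsd_mean, 0)
  expect_equal(cons2$provenance$averaged_volume_beads,
               sum(runs[[1]]$phase != "solvent"))

  # one outlier + near-identical majority: reference comes from the majority
  outlier <- runs[[2]]
  keep <- outlier$phase != "solvent"
  outlier$xyz[keep, 3] <- outlier$xyz[keep, 3] * 0.3   # squashed fake model
  ens <- c(rep(runs[1], 4), list(outlier))
  D <- sapply(ens, function(a) sapply(ens, function(b) nsd(a, b)))
  expect_equal(which.min(rowSums(D) / (length(ens) - 1)) <= 4, TRUE)
})
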