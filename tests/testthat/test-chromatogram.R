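test_that("elution profile is the per-frame mean intensity", {
  s <- seq(0.01, 0.1, length.out = 10)
  ser <- frame_series(s, cbind(rep(2, 10), rep(4, 10), rep(6, 10)),
                      matrix(0.1, 10, 3))
  expect_equal(build_elution_profile(ser), c(2, 4, 6))
  one <- frame_series(s, matrix(1, 10, 1), matrix(0.1, 10, 1))
  expect_equal(length(build_elution_profile(one)), 1)
  # mismatched grids are rejected (list-of-profiles path)
  p1 <- saxs_profile(s, rep(1, 10), rep(0.1, 10))
  p2 <- saxs_profile(s + 0.001, rep(1, 10), rep(0.1, 10))
  expect_error(build_elution_profile(list(p1, p2)), "mismatch")
})

test_that("region detection recovers the generator's ground truth", {
  sim <- small_series()
  truth <- sim$truth
  reg <- detect_regions(sim$series)
  # peak location
  expect_lte(abs(reg$peak_frames[1] - truth$peak_frame), 1)
  # buffer window lies (>= 90%) inside the true baseline
  buf <- reg$buffer_ranges[[1]]
  overlap <- max(0, min(buf[2], truth$buffer_range[2]) -
                   max(buf[1], truth$buffer_range[1]))
  expect_gte(overlap / (buf[2] - buf[1]), 0.9)
  # sample range contains its peak and roughly matches half-prominence truth
  sr <- reg$sample_ranges[[1]]
  expect_true(reg$peak_frames[1] >= sr[1] && reg$peak_frames[1] < sr[2])
  expect_lte(abs(sr[1] - truth$sample_range[1]), 6)
  expect_lte(abs(sr[2] - truth$sample_range[2]), 6)
})

test_that("region detection finds multiple peaks and rejects drift", {
  ph <- small_phantom()
  spec2 <- phantom_spec(protein_radius = 6, protein_height = 24, n_c = 8,
                        spacing = 3, s_grid = ph$oracle$s, frames = 600,
                        peak_frame = 200, peak_width = 18, seed = 12)
  sim <- simulate_frame_series(ph$oracle, spec2)
  ser <- sim$series
  gain2 <- 0.7 * exp(-((seq_len(600)) - 430)^2 / (2 * 18^2))
  ser <- frame_series(ser$s, ser$intensity + outer(ph$oracle$intensity, gain2),
                      ser$sigma)
  reg <- detect_regions(ser)
  expect_equal(length(reg$sample_ranges), 2)
  expect_lt(reg$peak_frames[1], reg$peak_frames[2])

  # strictly monotone drifting baseline: no peak
  set.seed(5)
  m <- 200; n <- 60
  base <- outer(rep(100, n), seq(1, 1.5, length.out = m))
  drift <- frame_series(seq(0.01, 0.2, length.out = n),
                        base + rnorm(n * m, 0, 0.5), matrix(0.5, n, m))
  expect_error(detect_regions(drift), "no sample peak")
})

test_that("averaging and subtraction are linear with propagated sigma", {
  s <- seq(0.01, 0.2, length.out = 50)
  buf <- matrix(100 * exp(-s * 5), 50, 20)
  sg <- matrix(1, 50, 20)
  ser_same <- frame_series(s, cbind(buf, buf), cbind(sg, sg))
  zero <- scale_and_subtract(ser_same, c(20L, 40L), c(0L, 20L))
  expect_equal(zero$intensity, rep(0, 50))
  expect_true(all(zero$sigma > 0))

  C <- 50 * exp(-(s * 20)^2 / 3)
  ser_c <- frame_series(s, cbind(buf, buf + C), cbind(sg, sg))
  rec <- scale_and_subtract(ser_c, c(20L, 40L), c(0L, 20L))
  expect_equal(rec$intensity, C, tolerance = 1e-12)

  # noisy generator series: recovery within 3 sigma pointwise at the peak
  sim <- small_series()
  truth <- sim$truth
  pk <- truth$peak_frame
  sub <- scale_and_subtract(sim$series, c(pk, pk + 1L),
                            c(0L, truth$buffer_range[2]))
  inj <- truth$gain[pk + 1L] * small_phantom()$oracle$intensity
  expect_true(all(abs(sub$intensity - inj) <= 3.5 * sub$sigma))
})

test_that("frame scaling and chi-square behave per the weighted model", {
  s <- seq(0.01, 0.3, length.out = 100)
  I <- 1000 * exp(-(s * 25)^2 / 3)
  ref <- saxs_profile(s, I, 0.02 * I)
  expect_equal(frame_chi2(ref, ref), list(c = 1, chi2 = 0))
  dbl <- saxs_profile(s, 2 * I, 0.04 * I)
  fc <- frame_chi2(ref, dbl)
  expect_equal(fc$c, 0.5)
  expect_equal(fc$chi2, 0)
  expect_error(frame_chi2(ref, saxs_profile(s, rep(0, 100), rep(1, 100))),
               "degenerate")

  # noisy frame at the recorded sigma: chi2 near 1 (n = 500)
  set.seed(42)
  n <- 500
  s2 <- seq(0.01, 0.3, length.out = n)
  I2 <- 1000 * exp(-(s2 * 25)^2 / 3)
  sg <- 0.02 * I2 + 1
  inside <- replicate(30, {
    r <- saxs_profile(s2, I2 + rnorm(n, 0, sg), sg)
    f <- saxs_profile(s2, I2 + rnorm(n, 0, sg), sg)
    frame_chi2(r, f)$chi2
  })
  expect_gte(mean(inside >= 0.8 & inside <= 1.2), 0.99 - 0.09) # binomial slack
})

test_that("mean frame chi-square calibrates to unity over seeded repetitions", {
  # m = 20 replicate frames vs a noisy reference, n = 500 points
  n <- 500; m <- 20
  s <- seq(0.01, 0.3, length.out = n)
  I <- 1000 * exp(-(s * 25)^2 / 3)
  sg <- 0.02 * I + 1
  reps <- vapply(1:20, function(seed) {
    set.seed(seed)
    ref <- saxs_profile(s, I + rnorm(n, 0, sg), sg)
    mean(vapply(seq_len(m), function(i) {
      fr <- saxs_profile(s, I + rnorm(n, 0, sg), sg)
      frame_chi2(ref, fr)$chi2
    }, numeric(1)))
  }, numeric(1))
  expect_gte(mean(reps >= 0.85 & reps <= 1.15), 0.95)
})

test_that("K combines c_v and <chi2> with the documented verdicts", {
  expect_equal(k_figure_of_merit(0.05, 10),
               list(K = 50, verdict = "low_quality"))
  expect_equal(k_figure_of_merit(0.01, 5)$verdict, "reliable")
  expect_equal(k_figure_of_merit(0.03, 5)$verdict, "caution")

  # full quality report on the generator series
  sim <- small_series()
  reg <- detect_regions(sim$series)
  sub <- scale_and_subtract(sim$series, reg$sample_ranges[[1]],
                            reg$buffer_ranges[[1]])
  q <- quality_K(sim$series, reg$sample_ranges[[1]], sub)
  expect_equal(q$K, 100 * q$c_v_aver * q$mean_chi2)
  expect_gte(q$mean_chi2, 0)
  expect_true(q$verdict %in% c("reliable", "caution", "low_quality"))

  # K is invariant under a global rescaling of intensities and sigmas
  ser10 <- frame_series(sim$series$s, 10 * sim$series$intensity,
                        10 * sim$series$sigma)
  sub10 <- scale_and_subtract(ser10, reg$sample_ranges[[1]],
                              reg$buffer_ranges[[1]])
  q10 <- quality_K(ser10, reg$sample_ranges[[1]], sub10)
  expect_equal(q10$K, q$K, tolerance = 1e-8)

  # identical noise-free frames + exact Guinier shape: chi2 = 0, K = 0
  s <- seq(0.005, 0.06, length.out = 60)
  Ig <- 100 * exp(-(s * 30)^2 / 3)
  serg <- frame_series(s, matrix(Ig, 60, 25), matrix(0.01 * Ig, 60, 25))
  qg <- quality_K(serg, c(0L, 25L), saxs_profile(s, Ig, 0.01 * Ig))
  expect_equal(qg$mean_chi2, 0)
  expect_equal(qg$K, 0)
  expect_equal(qg$verdict, "reliable")
})
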