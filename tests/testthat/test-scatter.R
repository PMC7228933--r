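test_that("Debye engine matches closed forms", {
  # single point with g = 2: I(0) = 4, I(s) = 4 Phi^2(s r)
  b1 <- scattering_body(matrix(0, 1, 3), 2, "p", c(p = 1), radius = 5)
  I <- debye_intensity(b1, c(0, 0.1, 0.2), binned = FALSE)$intensity
  ff <- function(x) (3 * (sin(x) - x * cos(x)) / x^3)^2
  expect_equal(I[1], 4)
  expect_equal(I[2], 4 * ff(0.5), tolerance = 1e-10)

  # two points, g = 1, d = 10, point radius -> 0
  b2 <- scattering_body(rbind(c(0, 0, 0), c(0, 0, 10)), 1, "p", c(p = 1))
  I2 <- debye_intensity(b2, c(0.05, 0.1), binned = FALSE)$intensity
  expect_equal(I2[2], 2 * (1 + sin(1) / 1), tolerance = 1e-10)

  # zero contrast everywhere -> identically 0
  b0 <- scattering_body(matrix(rnorm(30), 10, 3), 1, "p", c(p = 0))
  expect_equal(debye_intensity(b0, c(0.01, 0.1))$intensity, c(0, 0))

  # missing contrast errors
  expect_error(scattering_body(matrix(0, 1, 3), 1, "q", c(p = 1)),
               "phase without contrast")
})

test_that("binned Debye matches the exact R oracle within 0.5%", {
  set.seed(2)
  pts <- matrix(runif(3 * 3000, -25, 25), ncol = 3)
  pts <- pts[rowSums(pts^2) <= 625, ][1:600, ]
  g <- rep(1, 600)
  body <- scattering_body(pts, 1, "p", c(p = 1), radius = 1.5, spacing = 3)
  s <- seq(0.005, 0.3, length.out = 40)
  Ib <- debye_intensity(body, s)$intensity
  Ioracle <- debye_oracle_r(pts, g, 1.5, s)
  expect_lt(max(abs(Ib - Ioracle) / Ioracle), 0.005)
  # and the compiled exact path agrees with the R oracle to precision
  Ie <- debye_intensity(body, s, binned = FALSE)$intensity
  expect_equal(Ie, Ioracle, tolerance = 1e-10)
})

test_that("Debye intensity is invariant under rigid motions", {
  set.seed(3)
  pts <- matrix(rnorm(150, sd = 10), ncol = 3)
  body <- scattering_body(pts, 2, "p", c(p = 0.5), radius = 1)
  s <- seq(0.01, 0.3, length.out = 20)
  I0 <- debye_intensity(body, s, binned = FALSE)$intensity
  for (k in 1:3) {
    th <- runif(3, 0, 2 * pi)
    Rz <- rbind(c(cos(th[1]), -sin(th[1]), 0), c(sin(th[1]), cos(th[1]), 0), c(0, 0, 1))
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[2]), -sin(th[2])), c(0, sin(th[2]), cos(th[2])))
    moved <- sweep(pts %*% Rz %*% Rx, 2, runif(3, -20, 20), `+`)
    body2 <- scattering_body(moved, 2, "p", c(p = 0.5), radius = 1)
    I1 <- debye_intensity(body2, s, binned = FALSE)$intensity
    expect_equal(I1, I0, tolerance = 1e-6)
  }
})

test_that("corona filling respects exclusion, volume and lattice scaling", {
  toy <- make_toy_protein(3, 20)
  spec <- detergent_spec("C8H17", "C6H11O6")
  ap <- apriori_info(head_formula = "C6H11O6", tail_formula = "C8H17")
  ctr <- phase_densities(ap, spec)
  geom <- corona_start(spec)
  body <- fill_corona(toy, geom, ctr, spacing = 3)
  expect_setequal(unique(body$phase), c("protein", "tails", "heads"))

  # no corona point within the exclusion radius of any atom
  corona <- body$xyz[body$phase != "protein", , drop = FALSE]
  excl <- 1.7 + 3 / 2
  expect_false(any(points_near <- memsaxs:::points_near_cpp(corona, toy$xyz, excl)))

  # tail point count * spacing^3 matches the analytic torus-minus-protein
  # volume within 5% (Monte-Carlo overlap estimate)
  n_tail <- sum(body$phase == "tails")
  v_lattice <- n_tail * 27
  slab <- abs(toy$xyz[, 3]) <= geom$a / 2
  rho_at <- sqrt(toy$xyz[, 1]^2 + toy$xyz[, 2]^2)
  R_in <- as.numeric(quantile(rho_at[slab], 0.98))
  set.seed(6)
  n_mc <- 3e5
  Rout <- R_in + geom$b
  x <- runif(n_mc, -Rout, Rout); y <- runif(n_mc, -Rout, Rout)
  z <- runif(n_mc, -geom$a / 2, geom$a / 2)
  pts <- cbind(x, y, z)
  in_ring <- sqrt(x^2 + y^2) <= Rout
  near <- memsaxs:::points_near_cpp(pts, toy$xyz, excl)
  v_mc <- mean(in_ring & !near) * (2 * Rout)^2 * geom$a
  expect_lt(abs(v_lattice - v_mc) / v_mc, 0.05)

  # doubling the spacing reduces the point count ~8-fold
  fine <- fill_corona(toy, geom, ctr, spacing = 2.5)
  coarse <- fill_corona(toy, geom, ctr, spacing = 5)
  ratio <- sum(fine$phase != "protein") / sum(coarse$phase != "protein")
  expect_gt(ratio, 8 * 0.85)
  expect_lt(ratio, 8 * 1.15)
})

test_that("symmetry expansion replicates points and preserves intensity", {
  p <- matrix(c(10, 0, 0), 1, 3)
  out <- apply_symmetry(p, 4)
  expect_equal(nrow(out), 4)
  ang <- sort(atan2(out[, 2], out[, 1]) %% (2 * pi))
  expect_equal(ang, c(0, pi / 2, pi, 3 * pi / 2), tolerance = 1e-12)
  # axial point kept once
  expect_equal(nrow(apply_symmetry(matrix(c(0, 0, 5), 1, 3), 7)), 1)
  # n = 1 identity
  expect_equal(apply_symmetry(p, 1)[1, ], p[1, ], ignore_attr = TRUE)

  # Pn-symmetrized body scatters exactly like the explicit replica set
  set.seed(9)
  wedge <- cbind(runif(40, 2, 20), runif(40, 0.5, 5), runif(40, -10, 10))
  expanded <- apply_symmetry(wedge, 3)
  b1 <- scattering_body(expanded, 1, "p", c(p = 1), radius = 1)
  explicit <- do.call(rbind, lapply(0:2, function(k) {
    th <- 2 * pi * k / 3
    wedge %*% t(rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)))
  }))
  b2 <- scattering_body(explicit, 1, "p", c(p = 1), radius = 1)
  s <- seq(0.01, 0.25, length.out = 15)
  expect_equal(debye_intensity(b1, s, binned = FALSE)$intensity,
               debye_intensity(b2, s, binned = FALSE)$intensity,
               tolerance = 1e-12)
})

test_that("bead PDB files carry phases and round-trip coordinates", {
  ph <- small_phantom()
  f <- tempfile(fileext = ".pdb")
  write_bead_pdb(ph$body, f)
  lines <- readLines(f)
  expect_match(lines[1], "bead radius")
  expect_true(any(grepl("TAL", lines)))
  expect_true(any(grepl("HED", lines)))
  expect_equal(sum(grepl("^HETATM", lines)), nrow(ph$body$xyz))
})
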