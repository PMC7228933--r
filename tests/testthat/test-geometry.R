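test_that("Tanford length and derived corona starts are exact", {
  expect_equal(tanford_length(12), 16.68)
  expect_equal(tanford_length(0), 1.5)
  expect_equal(tanford_length(10), 14.15)
  expect_error(tanford_length(-1), "non-negative")
  # strictly increasing
  expect_true(all(diff(tanford_length(0:30)) > 0))

  ddm <- detergent_spec("C12H25", "C12H21O11")
  cs <- corona_start(ddm)
  expect_equal(cs$a, 16.68)
  expect_equal(cs$b, 16.68)
  expect_equal(cs$t, 16.68)
  expect_equal(cs$e, 1)
  expect_equal(cs$rotation, 0)
  expect_equal(cs$transmembrane_thickness, 33.36)
  expect_length(cs$warnings, 0)

  # long-tail detergent clamps at 45 A with a warning
  long <- detergent_spec("C22H45", "C12H21O11")
  csl <- corona_start(long)
  expect_equal(csl$transmembrane_thickness, 45)
  expect_true("THICKNESS_CLAMPED" %in% csl$warnings)

  # head-length override affects the grid, not the corona start
  over <- detergent_spec("C12H25", "C12H21O11", head_length = 8)
  expect_equal(corona_start(over)$t, 16.68)
  expect_equal(over$head_length, 8)
})

test_that("transmembrane diameter follows the subtraction formula exactly", {
  ddm <- detergent_spec("C12H25", "C12H21O11")
  expect_equal(transmembrane_diameter(100, ddm), 100 - 4 * 16.68)
  expect_error(transmembrane_diameter(66.72, ddm), "too small")
  dec <- detergent_spec("C10H21", "C12H21O11")
  expect_equal(transmembrane_diameter(120, dec), 120 - 4 * 14.15)
  # reconstruction identity
  d <- transmembrane_diameter(97.3, ddm)
  expect_equal(d + 2 * (ddm$head_length + ddm$tanford_tail), 97.3)
})

test_that("torus closed forms match Monte-Carlo sampling", {
  tm <- torus_metrics(30, 10, 1)
  expect_equal(tm$volume, 2 * pi^2 * 30 * 100, tolerance = 1e-12)
  expect_equal(torus_metrics(30, 0)$volume, 0)
  set.seed(11)
  for (k in 1:5) {
    R <- runif(1, 10, 40); r <- runif(1, 2, 0.8 * R); e <- runif(1, 0.8, 1.25)
    tm <- torus_metrics(R, r, e)
    n <- 4e5
    x <- runif(n, -(R + r), R + r); y <- runif(n, -(R + r), R + r)
    z <- runif(n, -r, r)
    inside <- (sqrt(x^2 + y^2) - R)^2 + z^2 <= r^2
    # apply the ellipticity scaling to the sampled torus
    xs <- e * x[inside]; ys <- y[inside] / e; zs <- z[inside]
    vol_mc <- mean(inside) * (2 * (R + r))^2 * 2 * r
    rg_mc <- sqrt(mean(xs^2 + ys^2 + zs^2))
    expect_lt(abs(tm$volume - vol_mc) / vol_mc, 0.02)
    expect_lt(abs(tm$rg - rg_mc) / rg_mc, 0.01)
    # hemi-torus (upper half) about its own centroid
    up <- zs > 0
    rg_hemi_mc <- sqrt(mean(xs[up]^2 + ys[up]^2 + (zs[up] - mean(zs[up]))^2))
    expect_lt(abs(tm$hemi_rg - rg_hemi_mc) / rg_hemi_mc, 0.01)
  }
})

test_that("confined corona-region metrics match Monte-Carlo sampling", {
  set.seed(12)
  R <- 9; r <- 11
  cm <- corona_region_metrics(R, r)
  n <- 6e5
  x <- runif(n, -(R + r), R + r); y <- runif(n, -(R + r), R + r)
  z <- runif(n, -r, r)
  rho <- sqrt(x^2 + y^2)
  inside <- rho >= R & (rho - R)^2 + z^2 <= r^2
  vol_mc <- mean(inside) * (2 * (R + r))^2 * 2 * r
  rg_mc <- sqrt(mean((x^2 + y^2 + z^2)[inside]))
  expect_lt(abs(cm$volume - vol_mc) / vol_mc, 0.02)
  expect_lt(abs(cm$rg - rg_mc) / rg_mc, 0.01)
})

test_that("phase densities come from formulae, sequence and overrides", {
  ddm <- detergent_spec("C12H25", "C12H21O11")
  ap <- apriori_info(head_formula = "C12H21O11", tail_formula = "C12H25")
  ctr <- phase_densities(ap, ddm)
  expect_equal(ctr$rho_tail, 97 / (27.4 + 26.9 * 12), tolerance = 1e-12)
  expect_equal(ctr$rho_buffer, 0.334)
  expect_equal(ctr$delta_tail, ctr$rho_tail - 0.334)
  expect_lt(ctr$delta_tail, 0)
  expect_gt(ctr$delta_head, 0)
  # direct override wins
  ap2 <- apriori_info(head_formula = "C12H21O11", tail_formula = "C12H25",
                      density_head = 0.52)
  ctr2 <- phase_densities(ap2, ddm)
  expect_equal(ctr2$delta_head, 0.52 - 0.334)
  # sequence-derived protein density is plausible
  ap3 <- apriori_info(sequence = "ACDEFGHIKLMNPQRSTVWY",
                      head_formula = "C12H21O11", tail_formula = "C12H25")
  ctr3 <- phase_densities(ap3, ddm)
  expect_gt(ctr3$rho_protein, 0.40)
  expect_lt(ctr3$rho_protein, 0.48)
})

test_that("search volume partitions the sphere with consistent region masks", {
  spec <- detergent_spec("C8H17", "C6H11O6")
  vol <- build_search_volume(62, spec, beads_per_diameter = 24)
  n <- nrow(vol$xyz)
  expect_true(all(sqrt(rowSums(vol$xyz^2)) <= 31 + 1e-6))
  expect_equal(length(vol$region), n)
  # every bead has exactly one label and a non-empty allowed set
  expect_true(all(vol$allowed > 0))
  # tails confined to |z| <= tanford + bead radius
  tails <- vol$region %in% c("tails", "boundary_12", "boundary_23")
  expect_true(all(abs(vol$xyz[tails, 3]) <= vol$tanford_tail + vol$r_bead + 1e-9))
  # fixed sphere sits inside the cylinder region
  fx <- vol$region == "fixed_protein_sphere"
  expect_true(all(sqrt(vol$xyz[fx, 1]^2 + vol$xyz[fx, 2]^2) <=
                    vol$R_cyl + 1e-9))
  expect_true(all(vol$fixed[fx]))

  # discretized region volumes match the analytic bodies within 7%
  counts <- table(vol$region)
  getc <- function(nm) if (nm %in% names(counts)) counts[[nm]] else 0
  v_tails <- (getc("tails") + 0.5 * (getc("boundary_12") + getc("boundary_23"))) *
    vol$v_cell
  a_tails <- corona_region_metrics(vol$R_cyl, vol$tanford_tail)$volume
  expect_lt(abs(v_tails - a_tails) / a_tails, 0.07)
  v_heads <- (getc("heads") + 0.5 * (getc("boundary_23") + getc("boundary_solvent"))) *
    vol$v_cell
  a_heads <- corona_region_metrics(vol$R_cyl,
                                   vol$tanford_tail + vol$head_length,
                                   vol$tanford_tail)$volume
  expect_lt(abs(v_heads - a_heads) / a_heads, 0.07)
  Rs <- vol$Dmax / 2
  v_cyl <- (getc("cylinder") + getc("fixed_protein_sphere") +
              0.5 * getc("boundary_12")) * vol$v_cell
  a_cyl <- (4 * pi / 3) * (Rs^3 - (Rs^2 - vol$R_cyl^2)^1.5)
  expect_lt(abs(v_cyl - a_cyl) / a_cyl, 0.07)

  expect_error(build_search_volume(62, spec, beads_per_diameter = 8),
               "too coarse")
})

test_that("region classification is rotationally symmetric about z", {
  spec <- detergent_spec("C8H17", "C6H11O6")
  vol <- build_search_volume(62, spec, beads_per_diameter = 16,
                             symmetry_order = 5)
  th <- 2 * pi / 5
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  lab_rot <- classify_corona_region(vol$xyz %*% t(rot), vol$R_cyl,
                                    vol$tanford_tail, vol$head_length,
                                    vol$fixed_sphere_radius, vol$r_bead,
                                    vol$Dmax)
  expect_equal(lab_rot, vol$region)
  # orbits group n symmetry mates (except axis beads)
  tab <- table(table(vol$orbit))
  expect_true(all(names(tab) %in% c("1", "5")))
})
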