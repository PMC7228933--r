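test_that("profile read/write round-trips and converts units", {
  s <- seq(0.01, 0.5, length.out = 500)
  p <- saxs_profile(s, exp(-s * 10) * 100, 0.01 * exp(-s * 10) * 100)
  f <- tempfile(fileext = ".dat")
  write_profile(p, f)
  q <- read_profile(f)
  expect_equal(length(q), 500)
  expect_equal(q$unit_tag, "inverse_angstrom")
  expect_equal(q$s, p$s, tolerance = 1e-6)
  expect_equal(q$intensity, p$intensity, tolerance = 1e-6)
  expect_equal(q$sigma, p$sigma, tolerance = 1e-6)

  # nm^-1 source: s = 1.0 nm^-1 stored as 0.1 A^-1; auto-detected
  f2 <- tempfile(fileext = ".dat")
  writeLines(c("# header", "1.0 10 0.1", "2.0 5 0.1", "3.0 2 0.1"), f2)
  q2 <- read_profile(f2)
  expect_equal(q2$unit_tag, "inverse_nanometre")
  expect_equal(q2$s[1], 0.1)
  # conversion is involutive
  expect_equal(q2$s * 10, c(1, 2, 3))
})

test_that("profile loading rejects degenerate input", {
  f <- tempfile(fileext = ".dat")
  writeLines("0.01 5 0.1", f)
  expect_error(read_profile(f), "too few")
  f2 <- tempfile(fileext = ".dat")
  writeLines(c("0.02 5 0.1", "0.01 6 0.1", "0.03 7 0.1"), f2)
  expect_error(read_profile(f2), "increasing.*row 2")
  expect_error(read_profile(tempfile()), "cannot read")
  # missing sigma column is synthesized and flagged
  f3 <- tempfile(fileext = ".dat")
  writeLines(c("0.01 5", "0.02 4", "0.03 3"), f3)
  p3 <- read_profile(f3)
  expect_true(p3$sigma_filled)
  expect_true(all(p3$sigma > 0))
})

test_that("chemical formulae parse and electron counts are additive", {
  expect_equal(parse_chemical_formula("C12H25"), c(C = 12L, H = 25L))
  expect_equal(electron_count("C12H25"), 97)
  expect_equal(electron_count("C12H21O11"), 181)
  expect_error(parse_chemical_formula("Xx3"), "unknown element")
  expect_error(parse_chemical_formula(""), "empty|invalid")
  # additivity over concatenation
  set.seed(1)
  parts <- c("C6H12O6", "NaCl", "C2H5OH", "SO4", "Fe2O3")
  for (i in 1:5) {
    pair <- sample(parts, 2)
    expect_equal(electron_count(paste0(pair[1], pair[2])),
                 electron_count(pair[1]) + electron_count(pair[2]))
  }
})

test_that("PDB reading handles altLoc, waters and element inference", {
  toy <- make_toy_protein(2, 6)
  f <- tempfile(fileext = ".pdb")
  write_atoms(toy, f)
  back <- read_atoms(f)
  expect_equal(nrow(back$xyz), nrow(toy$xyz))
  expect_equal(back$xyz, toy$xyz, tolerance = 1e-3, ignore_attr = TRUE)

  # altLoc A/B -> one copy kept
  lines <- c(
    "ATOM      1  CA AALA A   1      0.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA BALA A   1      0.500   0.000   0.000  0.50  0.00           C",
    "ATOM      3  CA  ALA A   2      3.800   0.000   0.000  1.00  0.00           C",
    "END")
  f2 <- tempfile(fileext = ".pdb")
  writeLines(lines, f2)
  a2 <- suppressWarnings(read_atoms(f2))
  expect_equal(nrow(a2$xyz), 2)

  # water-only file fails
  f3 <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1      0.000   0.000   0.000  1.00  0.00           O",
    "END"), f3)
  expect_error(suppressWarnings(read_atoms(f3)), "no protein atoms")
})

test_that("summary report writes XML + JSON twins and round-trips", {
  km <- k_figure_of_merit(0.05, 7)   # K = 35 -> low quality
  rep <- summary_report(
    peaks = list(list(
      buffer_range = c(0L, 20L), sample_range = c(40L, 60L),
      quality = list(K = km$K, verdict = km$verdict),
      warnings = list(make_warning("K_LOW_QUALITY")))),
    meta = list(seed = 1))
  base <- tempfile()
  paths <- write_summary(rep, base)
  expect_true(file.exists(paste0(base, ".xml")))
  doc <- xml2::read_xml(paste0(base, ".xml"))
  expect_equal(length(xml2::xml_find_all(doc, "//peak")), 1)
  # low-quality warning code present in both twins
  expect_match(paste(readLines(paste0(base, ".json")), collapse = ""),
               "K_LOW_QUALITY")
  back <- read_summary_json(paste0(base, ".json"))
  expect_equal(length(back$peaks), 1)
  expect_equal(back$peaks[[1]]$quality$K, km$K)
  expect_equal(back$peaks[[1]]$quality$verdict, "low_quality")
  expect_equal(unlist(back$peaks[[1]]$sample_range), c(40, 60),
               ignore_attr = TRUE)
})

test_that("frame bundle packs every frame plus a manifest", {
  sim <- small_series()
  sub <- frame_series(sim$series$s, sim$series$intensity[, 1:5],
                      sim$series$sigma[, 1:5])
  f <- tempfile(fileext = ".tar.gz")
  bundle_frames(sub, f)
  expect_true(file.exists(f))
  files <- utils::untar(f, list = TRUE)
  expect_equal(sum(grepl("frame_.*dat", files)), 5)
  expect_true(any(grepl("manifest.json", files)))
})
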