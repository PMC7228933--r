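# Shared fixtures, built in code and cached for the session.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- force(expr)
  fixture_cache[[key]]
}

# small phantom PDC (fast enough for unit tests)
small_phantom <- function() cached("small_phantom", {
  make_phantom_pdc(phantom_spec(
    protein_radius = 6, protein_height = 24, n_c = 8, spacing = 3,
    s_grid = seq(0.008, 0.25, length.out = 100),
    frames = 600, peak_frame = 300, peak_width = 25, seed = 11))
})

small_phantom_spec <- function() phantom_spec(
  protein_radius = 6, protein_height = 24, n_c = 8, spacing = 3,
  s_grid = seq(0.008, 0.25, length.out = 100),
  frames = 600, peak_frame = 300, peak_width = 25, seed = 11)

small_series <- function() cached("small_series", {
  simulate_frame_series(small_phantom()$oracle, small_phantom_spec())
})

# independent brute-force oracles --------------------------------------------

# exact Debye sum in plain R (independent of the compiled path)
debye_oracle_r <- function(xyz, g, radius, s) {
  D <- as.matrix(dist(xyz))
  ff <- function(x) ifelse(abs(x) < 1e-8, 1, 3 * (sin(x) - x * cos(x)) / x^3)
  vapply(s, function(sk) {
    S <- matrix(ifelse(abs(sk * D) < 1e-12, 1, sin(sk * D) / (sk * D)),
                nrow(D), ncol(D))
    sum((g %o% g) * S) * ff(sk * radius)^2
  }, numeric(1))
}

# brute-force Kozin-Svergun NSD in plain R
nsd_oracle_r <- function(A, B) {
  cross <- function(P, Q) mean(apply(P, 1, function(p) min(colSums((t(Q) - p)^2))))
  nnsp <- function(P) {
    D <- as.matrix(dist(P)); diag(D) <- Inf
    mean(apply(D, 1, min))
  }
  sqrt(0.5 * (cross(A, B) / nnsp(B)^2 + cross(B, A) / nnsp(A)^2))
}

# closed-form curve of a hollow spherical shell
shell_curve <- function(s, R1, R2, I0 = 1e6, rel_sigma = 0.02) {
  A <- function(s, R) {
    u <- s * R
    ifelse(u < 1e-8, (4 / 3) * pi * R^3,
           (4 / 3) * pi * R^3 * 3 * (sin(u) - u * cos(u)) / u^3)
  }
  amp <- A(s, R2) - A(s, R1)
  I <- I0 * (amp / amp[1])^2
  saxs_profile(s, I, pmax(rel_sigma * I, 1e-7 * I0))
}

quick_anneal_config <- function(seed = 1, ...) {
  anneal_config(seed = seed, sweeps_min = 20, sweeps_max = 40, stall = 8, ...)
}
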