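#' SEC-SAXS frame series
#'
#' Ordered collection of 1D frames on one common s grid: the raw material of
#' a SEC-SAXS run. Intensities and uncertainties are stored as
#' points-by-frames matrices; the per-frame integral intensity (mean of I
#' over the s grid) is the elution chromatogram.
#'
#' @param s common momentum-transfer grid (A^-1).
#' @param intensity n_s x m matrix of frame intensities.
#' @param sigma n_s x m matrix of 1-sigma uncertainties.
#' @return an object of class `frame_series`.
#' @export
frame_series <- function(s, intensity, sigma) {
  intensity <- as.matrix(intensity); sigma <- as.matrix(sigma)
  if (nrow(intensity) != length(s) || !all(dim(sigma) == dim(intensity)))
    stop("frame matrices must be n_points x n_frames and match s")
  structure(list(s = as.numeric(s), intensity = intensity, sigma = sigma,
                 integral_intensity = colMeans(intensity),
                 frame_count = ncol(intensity)),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("frame_series: %d frames x %d points, s in [%.4g, %.4g] A^-1\n",
              x$frame_count, length(x$s), min(x$s), max(x$s)))
  invisible(x)
}

#' Load a directory of frame profiles into a series
#'
#' Reads every `*.dat` file (sorted by name) and checks that all frames
#' share one s grid bitwise.
#'
#' @param dir directory of 3-column ASCII frames.
#' @param pattern filename pattern, default `"\\.dat$"`.
#' @return a [frame_series()].
#' @export
read_frame_series <- function(dir, pattern = "\\.dat$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0) stop("no frame files in ", dir)
  profs <- lapply(files, read_profile)
  s0 <- profs[[1]]$s
  for (i in seq_along(profs)) {
    if (!identical(profs[[i]]$s, s0))
      stop("frame s-grid mismatch: ", basename(files[i]),
           " differs from ", basename(files[1]))
  }
  frame_series(s0,
               vapply(profs, function(p) p$intensity, numeric(length(s0))),
               vapply(profs, function(p) p$sigma, numeric(length(s0))))
}

#' Extract one frame as a profile
#' @param series a [frame_series()].
#' @param i frame index (1-based).
#' @return a [saxs_profile()].
#' @export
series_frame <- function(series, i) {
  saxs_profile(series$s, series$intensity[, i], series$sigma[, i])
}

#' Build the elution profile (chromatogram)
#'
#' The per-frame integral intensity: arithmetic mean of I over the common
#' s grid, one value per frame.
#'
#' @param series a [frame_series()] (or a list of profiles on one grid).
#' @return numeric vector, one value per frame.
#' @export
build_elution_profile <- function(series) {
  if (inherits(series, "frame_series")) return(series$integral_intensity)
  # list of profiles: validate the common grid first
  s0 <- series[[1]]$s
  for (i in seq_along(series)) {
    if (!identical(series[[i]]$s, s0))
      stop("frame s-grid mismatch at frame ", i)
  }
  vapply(series, function(p) mean(p$intensity), numeric(1))
}

#' Identify buffer and sample regions of a SEC-SAXS chromatogram
#'
#' The buffer is the flattest low stretch: a sliding window (width
#' `max(10, m/40)`) minimizing window mean + lambda * |slope| * width +
#' lambda2 * standard deviation of the integral intensity. Sample peaks
#' are contiguous stretches exceeding baseline + 5 x baseline noise;
#' each peak's reported range is cut at half prominence. All peaks above
#' threshold are returned, in elution order. Intervals are half-open
#' `[start, end)` in 0-based frame indices.
#'
#' @param series a [frame_series()].
#' @param lambda,lambda2 weights for slope and spread in the buffer score.
#' @param smooth odd width of the running-mean smoother used for peak
#'   detection.
#' @return list with `buffer_ranges`, `sample_ranges` (lists of c(start,
#'   end) 0-based half-open), `peak_frames` (0-based), `baseline`, `noise`.
#' @export
detect_regions <- function(series, lambda = 2, lambda2 = 2, smooth = 5) {
  v <- build_elution_profile(series)
  m <- length(v)
  if (m < 20) stop("need at least 20 frames to detect regions")
  w <- max(10L, m %/% 40L)
  # sliding-window flatness score
  idx <- seq_len(m - w + 1L)
  cs <- cumsum(c(0, v))
  wmean <- (cs[idx + w] - cs[idx]) / w
  t0 <- seq_len(w) - (w + 1) / 2
  stt <- sum(t0^2)
  slope <- vapply(idx, function(i) sum(v[i:(i + w - 1)] * t0) / stt, numeric(1))
  wsd <- vapply(idx, function(i) sd(v[i:(i + w - 1)]), numeric(1))
  score <- wmean + lambda * abs(slope) * w + lambda2 * wsd
  b0 <- which.min(score)
  # prefer the earliest window whose score is indistinguishable from the
  # minimum (pre-peak buffer, the usual SEC-SAXS situation)
  tol <- max(wsd[b0], .Machine$double.eps * max(abs(v)))
  b0 <- which(score <= score[b0] + tol)[1]
  baseline <- wmean[b0]
  noise <- wsd[b0]
  spread <- diff(range(v))
  if (!is.finite(noise) || (spread > 0 && wsd[b0] + abs(slope[b0]) * w > 0.5 * spread))
    stop("no buffer region: chromatogram has no flat stretch")
  buffer_range <- c(b0 - 1L, b0 - 1L + w)   # 0-based half-open
  # peak detection on a lightly smoothed trace
  k <- rep(1 / smooth, smooth)
  vs <- as.numeric(stats::filter(v, k, sides = 2))
  vs[is.na(vs)] <- v[is.na(vs)]
  thr <- baseline + 5 * max(noise, .Machine$double.eps * max(abs(v), 1))
  above <- vs > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  sample_ranges <- list(); peak_frames <- integer(0)
  for (r in which(runs$values & runs$lengths >= 3)) {
    a <- starts[r]; b <- ends[r]
    pk <- a - 1L + which.max(v[a:b])
    half <- baseline + 0.5 * (vs[pk] - baseline)
    # half-prominence boundaries must exist on both sides (otherwise it is
    # a drifting baseline or truncated elution, not a resolved peak)
    lo <- pk; while (lo > 1 && vs[lo - 1] >= half) lo <- lo - 1L
    hi <- pk; while (hi < m && vs[hi + 1] >= half) hi <- hi + 1L
    if (lo == 1 && vs[1] >= half) next
    if (hi == m && vs[m] >= half) next
    sample_ranges[[length(sample_ranges) + 1L]] <- c(lo - 1L, hi)  # 0-based half-open
    peak_frames <- c(peak_frames, pk - 1L)
  }
  if (length(sample_ranges) == 0) stop("no sample peak above threshold")
  list(buffer_ranges = list(buffer_range), sample_ranges = sample_ranges,
       peak_frames = peak_frames, baseline = baseline, noise = noise)
}

avg_frames <- function(series, frames1) {
  I <- series$intensity[, frames1, drop = FALSE]
  S <- series$sigma[, frames1, drop = FALSE]
  w <- 1 / S^2
  sw <- rowSums(w)
  list(I = rowSums(I * w) / sw, sigma = sqrt(1 / sw))
}

#' Average sample and buffer frames and subtract
#'
#' Frames of each set are averaged pointwise with inverse-variance weights;
#' the result is sample average minus buffer average with uncertainties
#' propagated in quadrature.
#'
#' @param series a [frame_series()].
#' @param sample_range,buffer_range c(start, end) 0-based half-open frame
#'   intervals (as returned by [detect_regions()]).
#' @return a [saxs_profile()] of the purified component.
#' @export
scale_and_subtract <- function(series, sample_range, buffer_range) {
  sf <- (sample_range[1] + 1L):sample_range[2]
  bf <- (buffer_range[1] + 1L):buffer_range[2]
  if (length(sf) == 0 || length(bf) == 0) stop("empty frame set")
  smp <- avg_frames(series, sf)
  buf <- avg_frames(series, bf)
  saxs_profile(series$s, smp$I - buf$I, sqrt(smp$sigma^2 + buf$sigma^2))
}

#' Scale and chi-square of one frame against the peak frame
#'
#' The scaling coefficient minimizing the weighted squared deviation of the
#' frame from the reference is found by closed-form weighted least squares
#' with weights `1/sigma_p^2`, followed by one re-weighting iteration with
#' the combined variance `sigma_p^2 + c^2 sigma_l^2`. The reported
#' chi-square is `(1/(n-1)) * sum[(I_p - c I_l)^2 / (sigma_p^2 + c^2
#' sigma_l^2)]`.
#'
#' @param reference the peak frame (maximum integral intensity), a
#'   [saxs_profile()].
#' @param frame another frame on the same grid.
#' @return list with `c` (scale) and `chi2`.
#' @export
frame_chi2 <- function(reference, frame) {
  if (!isTRUE(all.equal(reference$s, frame$s)))
    stop("frames must share one s grid")
  n <- length(reference$s)
  if (n < 2) stop("need at least 2 points")
  Ip <- reference$intensity; sp2 <- reference$sigma^2
  Il <- frame$intensity; sl2 <- frame$sigma^2
  if (all(Il == 0)) stop("degenerate frame: all intensities zero")
  cl <- sum(Ip * Il / sp2) / sum(Il^2 / sp2)
  v <- sp2 + cl^2 * sl2
  cl <- sum(Ip * Il / v) / sum(Il^2 / v)
  v <- sp2 + cl^2 * sl2
  chi2 <- sum((Ip - cl * Il)^2 / v) / (n - 1)
  list(c = cl, chi2 = chi2)
}

#' K figure of merit from its two components
#'
#' `K = 100% * c_v^aver * <chi^2>`: the coefficient of variation of the
#' Guinier radius of gyration of the subtracted curve times the mean frame
#' chi-square across the elution peak. `K < 10%` indicates reliable data;
#' `K >= 30%` flags low quality; values between call for caution.
#'
#' @param c_v coefficient of variation `sigma_Rg / Rg` of the subtracted
#'   curve's Guinier fit.
#' @param mean_chi2 mean frame chi-square across the peak.
#' @return list with `K` (percent) and `verdict`.
#' @export
k_figure_of_merit <- function(c_v, mean_chi2) {
  K <- 100 * c_v * mean_chi2
  verdict <- if (K < 10) "reliable" else if (K >= 30) "low_quality" else "caution"
  list(K = K, verdict = verdict)
}

#' Data-quality report for one elution peak
#'
#' Computes `<chi^2>` (mean frame chi-square of all frames in the sample
#' range against the peak frame, the peak frame contributing zero),
#' `c_v^aver` (`sigma_Rg/Rg` of the subtracted curve's Guinier fit) and the
#' K figure of merit with its verdict.
#'
#' @param series a [frame_series()].
#' @param sample_range c(start, end), 0-based half-open.
#' @param subtracted the averaged, buffer-subtracted [saxs_profile()].
#' @return object of class `quality_report`: `c_v_aver`, `mean_chi2`, `K`,
#'   `verdict`, `warnings`, `peak_frame` (0-based), `frame_chi2` vector.
#' @export
quality_K <- function(series, sample_range, subtracted) {
  sf <- (sample_range[1] + 1L):sample_range[2]
  if (length(sf) < 2) stop("need at least 2 sample frames")
  peak1 <- sf[which.max(series$integral_intensity[sf])]
  ref <- series_frame(series, peak1)
  chis <- vapply(sf, function(i) {
    if (i == peak1) return(0)
    frame_chi2(ref, series_frame(series, i))$chi2
  }, numeric(1))
  mean_chi2 <- mean(chis)
  warnings <- character(0)
  gfit <- tryCatch(guinier_fit(subtracted), error = function(e) e)
  if (inherits(gfit, "error")) {
    warnings <- c(warnings, "GUINIER_FAIL")
    rep <- list(c_v_aver = NA_real_, mean_chi2 = mean_chi2, K = NA_real_,
                verdict = "low_quality", warnings = warnings,
                peak_frame = peak1 - 1L, frame_chi2 = chis)
    return(structure(rep, class = "quality_report"))
  }
  c_v <- gfit$sigma_Rg / gfit$Rg
  km <- k_figure_of_merit(c_v, mean_chi2)
  if (km$verdict == "low_quality") warnings <- c(warnings, "K_LOW_QUALITY")
  if (km$verdict == "caution") warnings <- c(warnings, "K_CAUTION")
  if (isTRUE(subtracted$sigma_filled)) warnings <- c(warnings, "SIGMA_FILLED")
  structure(list(c_v_aver = c_v, mean_chi2 = mean_chi2, K = km$K,
                 verdict = km$verdict, warnings = warnings,
                 peak_frame = peak1 - 1L, frame_chi2 = chis,
                 guinier = gfit),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("K = %.2f%% (c_v = %.4f, <chi2> = %.3f) -> %s\n",
              x$K, x$c_v_aver, x$mean_chi2, x$verdict))
  invisible(x)
}
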