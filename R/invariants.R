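#' Guinier fit with automatic range selection
#'
#' Fits `ln I` vs `s^2` at low angle. The fit window is found iteratively:
#' starting from an initial slope estimate on the lowest usable points, the
#' window is restricted to points satisfying the standard validity bounds
#' `srg_min <= s*Rg <= srg_max` (default 0.5 and 1.3) and re-fit until the
#' window is stable. A sign-runs test on the residuals (5% level) screens
#' for systematic curvature; while it fails, the window is shrunk from the
#' high-s end.
#'
#' @param profile a [saxs_profile()].
#' @param srg_min,srg_max dimensionless bounds on `s*Rg` for the window.
#' @return list of class `guinier_result`: `Rg`, `I0`, `sigma_Rg`,
#'   `sigma_I0`, `fit_idx`, `s_range`, `sRg_min`, `sRg_max`, `npts`,
#'   `residuals`.
#' @export
guinier_fit <- function(profile, srg_min = 0.5, srg_max = 1.3) {
  ok <- profile$intensity > 0
  if (sum(ok) < 10) stop("no valid Guinier region: fewer than 10 positive points")
  s <- profile$s; I <- profile$intensity; sg <- profile$sigma
  fit_window <- function(idx) {
    x <- s[idx]^2; y <- log(I[idx])
    wts <- (I[idx] / sg[idx])^2          # delta-method weights for ln I
    f <- lm(y ~ x, weights = wts)
    list(slope = coef(f)[[2]], intercept = coef(f)[[1]],
         se_slope = summary(f)$coefficients[2, 2],
         se_int = summary(f)$coefficients[1, 2],
         resid = stats::residuals(f))
  }
  # initial estimate on the lowest positive points
  low <- which(ok)[seq_len(min(max(10, sum(ok) %/% 10), sum(ok)))]
  f0 <- fit_window(low)
  if (f0$slope >= 0) stop("no valid Guinier region: intensity does not decay at low s")
  Rg <- sqrt(-3 * f0$slope)
  idx_old <- integer(0)
  for (it in 1:25) {
    idx <- which(ok & s * Rg >= srg_min & s * Rg <= srg_max)
    if (length(idx) < 5) {
      # very small particles or truncated low-s: allow the window to start
      # at the first usable point even below the lower bound
      idx <- which(ok & s * Rg <= srg_max)[seq_len(min(10, sum(ok)))]
      idx <- idx[!is.na(idx)]
    }
    if (length(idx) < 5) stop("no valid Guinier region: window too short")
    f <- fit_window(idx)
    if (f$slope >= 0) stop("no valid Guinier region: non-negative slope")
    Rg <- sqrt(-3 * f$slope)
    if (identical(idx, idx_old)) break
    idx_old <- idx
  }
  # curvature screen: Wald-Wolfowitz runs test on residual signs
  runs_ok <- function(r) {
    sgn <- sign(r); sgn <- sgn[sgn != 0]
    n1 <- sum(sgn > 0); n2 <- sum(sgn < 0)
    if (n1 == 0 || n2 == 0) return(FALSE)
    runs <- 1 + sum(diff(sgn) != 0)
    mu <- 1 + 2 * n1 * n2 / (n1 + n2)
    v <- 2 * n1 * n2 * (2 * n1 * n2 - n1 - n2) /
      ((n1 + n2)^2 * (n1 + n2 - 1))
    if (v <= 0) return(TRUE)
    abs((runs - mu) / sqrt(v)) < 1.96
  }
  while (length(idx) > 8 && !runs_ok(f$resid)) {
    idx <- idx[-length(idx)]
    f <- fit_window(idx)
    if (f$slope >= 0) stop("no valid Guinier region: non-negative slope")
    Rg <- sqrt(-3 * f$slope)
  }
  # final trim so the reported window satisfies the validity bounds with the
  # final Rg (the screen above may have nudged Rg slightly)
  for (it in 1:10) {
    drop_lo <- length(idx) > 5 && s[idx[1]] * Rg < srg_min
    drop_hi <- length(idx) > 5 && s[idx[length(idx)]] * Rg > srg_max
    if (!drop_lo && !drop_hi) break
    if (drop_lo) idx <- idx[-1]
    if (drop_hi) idx <- idx[-length(idx)]
    f <- fit_window(idx)
    if (f$slope >= 0) stop("no valid Guinier region: non-negative slope")
    Rg <- sqrt(-3 * f$slope)
  }
  sigma_Rg <- 3 * f$se_slope / (2 * Rg)
  I0 <- exp(f$intercept)
  structure(list(Rg = Rg, I0 = I0, sigma_Rg = sigma_Rg,
                 sigma_I0 = I0 * f$se_int,
                 fit_idx = range(idx), s_range = s[range(idx)],
                 sRg_min = s[idx[1]] * Rg, sRg_max = s[idx[length(idx)]] * Rg,
                 npts = length(idx), residuals = f$resid),
            class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("Guinier: Rg = %.2f +/- %.2f A, I0 = %.4g, sRg in [%.2f, %.2f] (%d pts)\n",
              x$Rg, x$sigma_Rg, x$I0, x$sRg_min, x$sRg_max, x$npts))
  invisible(x)
}

ift_design <- function(s, dmax, nr) {
  r_in <- dmax * (seq_len(nr) - 0.5) / nr   # bin centres, p = 0 at 0 and dmax
  dr <- dmax / nr
  A <- 4 * pi * dr * outer(s, r_in, function(sk, rj) {
    x <- sk * rj
    ifelse(abs(x) < 1e-10, 1, sin(x) / x)
  })
  D2 <- diff(diag(nr + 2), differences = 2)[, 2:(nr + 1)]  # p = 0 beyond ends
  list(A = A, D2 = D2, r_in = r_in, dr = dr)
}

ift_solve <- function(des, I, sg, alpha) {
  Aw <- des$A / sg
  yw <- I / sg
  M <- crossprod(Aw) + alpha * crossprod(des$D2)
  p <- tryCatch(solve(M, crossprod(Aw, yw)), error = function(e) NULL)
  if (is.null(p)) return(NULL)
  p <- drop(p)
  resid2 <- sum((drop(des$A %*% p) - I)^2 / sg^2)
  list(p = p, chi2_red = resid2 / max(1, length(I) - 1),
       seminorm = sum(drop(des$D2 %*% p)^2))
}

ift_alpha_lcurve <- function(des, I, sg) {
  alphas <- 10^seq(-8, 6, length.out = 29) * length(I)
  rho <- eta <- rep(NA_real_, length(alphas))
  sols <- vector("list", length(alphas))
  for (i in seq_along(alphas)) {
    sol <- ift_solve(des, I, sg, alphas[i])
    if (is.null(sol)) next
    sols[[i]] <- sol
    rho[i] <- log(max(sol$chi2_red, 1e-300))
    eta[i] <- log(max(sol$seminorm, 1e-300))
  }
  ok <- which(is.finite(rho) & is.finite(eta))
  if (length(ok) < 5) stop("indirect transform ill-conditioned beyond recovery")
  # L-curve corner: maximum curvature of (rho, eta) along the alpha path
  kmax <- -Inf; best <- ok[ceiling(length(ok) / 2)]
  for (j in ok[-c(1, length(ok))]) {
    jm <- max(ok[ok < j]); jp <- min(ok[ok > j])
    d1x <- (rho[jp] - rho[jm]) / 2; d1y <- (eta[jp] - eta[jm]) / 2
    d2x <- rho[jp] - 2 * rho[j] + rho[jm]
    d2y <- eta[jp] - 2 * eta[j] + eta[jm]
    denom <- (d1x^2 + d1y^2)^1.5
    if (denom <= 0) next
    kcur <- (d1x * d2y - d1y * d2x) / denom
    if (is.finite(kcur) && kcur > kmax) { kmax <- kcur; best <- j }
  }
  list(alpha = alphas[best], sol = sols[[best]])
}

#' Pair-distance distribution P(r) by regularized indirect transform
#'
#' Represents P(r) on a histogram basis of `nr` shells on `[0, Dmax]` with
#' P forced to zero at both ends, and solves the smoothness-regularized
#' (second-derivative penalty) weighted least-squares problem; the
#' regularization weight is chosen at the L-curve corner. When no
#' `dmax_hint` is given, Dmax is scanned on a geometric grid `[2Rg, 5Rg]`
#' and the smallest value whose solution stays non-negative (within -1% of
#' the maximum) with a stable real-space Rg is chosen.
#'
#' @param profile a [saxs_profile()] (buffer-subtracted curve).
#' @param dmax_hint optional maximum dimension in Angstrom.
#' @param nr number of r shells (default 50).
#' @return list of class `pr_result`: `r`, `p` (with the zero end points),
#'   `Dmax`, `Rg_real`, `I0_real`, `alpha`, `chi2_red`, `negativity`.
#' @export
pr_transform <- function(profile, dmax_hint = NULL, nr = 50) {
  s <- profile$s
  # work on a unit intensity scale so the estimator is exactly invariant to
  # rescaling; the forward intensity is restored at the end
  nrm <- max(abs(profile$intensity))
  I <- profile$intensity / nrm
  sg <- profile$sigma / nrm
  solve_at <- function(dmax) {
    des <- ift_design(s, dmax, nr)
    pick <- ift_alpha_lcurve(des, I, sg)
    p <- pick$sol$p
    qint <- sum(p) * des$dr
    rg2 <- sum(des$r_in^2 * p) * des$dr / (2 * qint)
    list(dmax = dmax, p = p, r_in = des$r_in, dr = des$dr,
         alpha = pick$alpha, chi2_red = pick$sol$chi2_red,
         rg = if (rg2 > 0) sqrt(rg2) else NA_real_,
         i0 = 4 * pi * qint,
         neg = if (max(p) > 0) min(p) / max(p) else 0,
         endfrac = if (max(p) > 0) p[length(p)] / max(p) else 0)
  }
  if (!is.null(dmax_hint)) {
    best <- solve_at(dmax_hint)
  } else {
    g <- guinier_fit(profile)
    dgrid <- exp(seq(log(2 * g$Rg), log(5 * g$Rg), length.out = 12))
    sols <- lapply(dgrid, function(d) tryCatch(solve_at(d), error = function(e) NULL))
    keep <- !vapply(sols, is.null, logical(1))
    sols <- sols[keep]
    if (length(sols) == 0) stop("indirect transform ill-conditioned beyond recovery")
    rgs <- vapply(sols, function(x) x$rg, numeric(1))
    negs <- vapply(sols, function(x) x$neg, numeric(1))
    ends <- vapply(sols, function(x) x$endfrac, numeric(1))
    best <- NULL
    for (i in seq_along(sols)) {
      stable <- if (i < length(sols))
        is.finite(rgs[i]) && abs(rgs[i + 1] - rgs[i]) / rgs[i] < 0.02 else TRUE
      # P must come down gently at Dmax: a large last-shell value means the
      # zero endpoint is truncating real pair distances
      if (negs[i] >= -0.01 && ends[i] <= 0.05 && stable) { best <- sols[[i]]; break }
    }
    if (is.null(best)) best <- sols[[which.max(negs)]]
  }
  structure(list(r = c(0, best$r_in, best$dmax),
                 p = nrm * c(0, best$p, 0),
                 Dmax = best$dmax, Rg_real = best$rg, I0_real = nrm * best$i0,
                 alpha = best$alpha, chi2_red = best$chi2_red,
                 negativity = best$neg,
                 flagged_negative = best$neg < -0.01),
            class = "pr_result")
}

#' @export
print.pr_result <- function(x, ...) {
  cat(sprintf("P(r): Dmax = %.1f A, Rg(real) = %.2f A, I0 = %.4g, chi2 = %.2f\n",
              x$Dmax, x$Rg_real, x$I0_real, x$chi2_red))
  invisible(x)
}

#' Porod volume and apparent molecular weight
#'
#' Fits a constant background B by regressing I on s^-4 over the high-s
#' tail (Porod regime), forms the Porod invariant `Q = int s^2 (I - B) ds`
#' with an analytic Guinier extension below the first data point and a
#' `K_p/s_max` tail extension, and returns `V_Porod = 2 pi^2 I0 / Q`.
#' The molecular weight uses the common empirical conversion
#' `MW[Da] = V_Porod[A^3] / 1.6`, reported as *apparent* because detergent
#' contributions bias it for protein-detergent complexes.
#'
#' @param profile a [saxs_profile()].
#' @param I0,Rg forward intensity and radius of gyration (from
#'   [guinier_fit()]).
#' @param tail_fraction fraction of the high-s points used for the
#'   background fit.
#' @return list with `V_porod` (A^3), `MW_kda`, `Q`, `background`.
#' @export
porod_volume_mw <- function(profile, I0, Rg, tail_fraction = 0.25) {
  s <- profile$s; I <- profile$intensity
  n <- length(s)
  tail <- seq.int(max(1L, floor(n * (1 - tail_fraction))), n)
  fit <- lm(I[tail] ~ I(s[tail]^-4))
  B <- coef(fit)[[1]]
  B <- min(B, min(I[tail]))          # background cannot exceed the data
  B <- max(B, 0)
  # Porod constant from the tail mean of s^4 (I - B) (robust to the
  # oscillations of compact-particle curves)
  Kp <- max(mean(s[tail]^4 * (I[tail] - B)), 0)
  y <- s^2 * (I - B)
  Qdata <- sum(diff(s) * (y[-1] + y[-n]) / 2)
  if (Qdata <= sqrt(.Machine$double.eps) * max(s)^3 * max(abs(I)))
    stop("Porod invariant vanishes after background removal")
  Qlow <- integrate(function(x) x^2 * I0 * exp(-(x * Rg)^2 / 3),
                    0, s[1])$value
  Qtail <- if (Kp > 0) Kp / s[n] else 0
  Q <- Qdata + Qlow + Qtail
  V <- 2 * pi^2 * I0 / Q
  list(V_porod = V, MW_kda = V / 1.6 / 1000, Q = Q, background = B,
       apparent = TRUE)
}

#' Automatic s_max from the first minimum of the curve
#'
#' Smooths log-intensity with a Savitzky-Golay filter (local quadratic,
#' default 11-point window) and returns the s of the first local minimum
#' that is at least `min_depth` deep relative to the following maximum.
#' If no such minimum occurs, or it lies beyond the ceiling, the ceiling is
#' returned (ab initio shape reconstruction typically uses s_max below
#' 0.1 A^-1).
#'
#' @param profile a [saxs_profile()] with at least 30 points.
#' @param ceiling upper bound on the returned value (A^-1).
#' @param window odd Savitzky-Golay window length.
#' @param min_depth minimum relative depth of the dip (intensity ratio - 1).
#' @return s_max in A^-1, never above `ceiling`.
#' @export
first_minimum_smax <- function(profile, ceiling = 0.10, window = 11,
                               min_depth = 0.03) {
  s <- profile$s; I <- profile$intensity
  if (length(s) < 30) stop("need at least 30 points")
  y <- log(pmax(I, max(I) * 1e-12))
  ys <- signal::sgolayfilt(y, p = 2, n = window)
  n <- length(ys)
  for (i in 3:(n - 2)) {
    if (ys[i] < ys[i - 1] && ys[i] <= ys[i + 1]) {
      # following local maximum (or end of data)
      j <- i + 1
      while (j < n && ys[j + 1] >= ys[j]) j <- j + 1
      depth <- exp(ys[j] - ys[i]) - 1
      if (depth >= min_depth) return(min(s[i], ceiling))
    }
  }
  ceiling
}
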