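#' One-dimensional SAXS profile
#'
#' A scattering profile holds the momentum transfer grid `s` (stored in
#' inverse Angstrom, ascending), intensities `intensity` in arbitrary units
#' and 1-sigma uncertainties `sigma`. `unit_tag` records the unit of the
#' source the profile was loaded from (`"inverse_angstrom"` or
#' `"inverse_nanometre"`); internally `s` is always in inverse Angstrom.
#'
#' @param s numeric vector of momentum-transfer values, strictly increasing.
#' @param intensity numeric vector, same length as `s`.
#' @param sigma optional numeric vector of 1-sigma uncertainties. When
#'   absent it is filled with `max(0.01 * |I|, eps)` and the profile is
#'   flagged (`sigma_filled` attribute) so reports can surface it.
#' @param unit_tag unit of the source data for `s`.
#' @return an object of class `saxs_profile`.
#' @export
saxs_profile <- function(s, intensity, sigma = NULL,
                         unit_tag = c("inverse_angstrom", "inverse_nanometre")) {
  unit_tag <- match.arg(unit_tag)
  s <- as.numeric(s); intensity <- as.numeric(intensity)
  if (length(s) != length(intensity))
    stop("s and intensity must have equal length")
  if (length(s) < 2) stop("too few points: a profile needs at least 2 rows")
  d <- diff(s)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1] + 1L
    stop(sprintf("s must be strictly increasing (violated at row %d)", bad))
  }
  sigma_filled <- FALSE
  if (is.null(sigma)) {
    floor_sig <- 1e3 * .Machine$double.eps * max(abs(intensity), 1)
    sigma <- pmax(0.01 * abs(intensity), floor_sig)
    sigma_filled <- TRUE
  } else {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(s)) stop("sigma length mismatch")
  }
  structure(
    list(s = s, intensity = intensity, sigma = sigma,
         unit_tag = unit_tag, sigma_filled = sigma_filled),
    class = "saxs_profile")
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("saxs_profile: %d points, s in [%.4g, %.4g] A^-1 (source %s)\n",
              length(x$s), min(x$s), max(x$s), x$unit_tag))
  invisible(x)
}

#' @export
length.saxs_profile <- function(x) length(x$s)

#' Restrict a profile to an s-range or point subset
#' @param x a `saxs_profile`.
#' @param idx integer or logical index into the points.
#' @return a `saxs_profile` on the subset.
#' @export
profile_subset <- function(x, idx) {
  saxs_profile(x$s[idx], x$intensity[idx],
               x$sigma[idx], unit_tag = x$unit_tag)
}

#' Read a 1D SAXS profile from 3-column ASCII
#'
#' Reads `s, I[, sigma]` columns from a whitespace-separated text file.
#' Lines starting with `#` and lines that do not parse as numbers (headers,
#' footers) are skipped. `s` is converted to inverse Angstrom on load:
#' a file in inverse nanometre is divided by 10. The unit is taken from
#' `unit_hint` when given, otherwise auto-detected (`max(s) > 2` is taken to
#' mean inverse nanometre, since SAXS data rarely extend beyond 2 A^-1).
#'
#' @param path file to read.
#' @param unit_hint optional `"inverse_angstrom"` or `"inverse_nanometre"`.
#' @return a [saxs_profile()].
#' @export
read_profile <- function(path, unit_hint = NULL) {
  if (!file.exists(path)) stop("cannot read profile: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s*#", lines)]
  rows <- lapply(strsplit(trimws(lines), "\\s+"), function(f) {
    v <- suppressWarnings(as.numeric(f))
    if (length(v) >= 2 && !anyNA(v[1:min(3, length(v))])) v[1:min(3, length(v))] else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) < 2) stop("too few points: fewer than 2 parseable data rows in ", path)
  ncol <- min(vapply(rows, length, integer(1)))
  m <- t(vapply(rows, function(r) r[seq_len(ncol)], numeric(ncol)))
  s <- m[, 1]
  unit <- unit_hint %||% if (max(s) > 2) "inverse_nanometre" else "inverse_angstrom"
  if (unit == "inverse_nanometre") s <- s / 10
  sigma <- if (ncol >= 3) {
    sg <- m[, 3]
    if (unit == "inverse_nanometre") sg else sg   # sigma shares I's units
  } else NULL
  saxs_profile(s, m[, 2], sigma, unit_tag = unit)
}

#' Write a profile as 3-column ASCII
#'
#' Writes `s` (inverse Angstrom), `I`, `sigma` with a `#` header; the inverse
#' of [read_profile()] to six significant digits.
#'
#' @param profile a `saxs_profile`.
#' @param path destination file.
#' @param header optional extra comment line.
#' @export
write_profile <- function(profile, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines("# s(1/A)  I(s)  sigma", con)
  writeLines(sprintf("%.6e %.6e %.6e",
                     profile$s, profile$intensity, profile$sigma), con)
  invisible(path)
}
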