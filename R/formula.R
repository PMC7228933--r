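#' Parse a chemical formula into element counts
#'
#' Accepts compact formulae such as `"C12H25"` or `"C12H21O11"`: repeated
#' (element symbol, optional count) tokens. Counts default to 1. Repeated
#' element symbols are summed.
#'
#' @param text formula string.
#' @return named integer vector of element counts.
#' @export
parse_chemical_formula <- function(text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text)))
    stop("empty or invalid formula")
  text <- trimws(text)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  toks <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
  if (sum(nchar(toks)) != nchar(text))
    stop("cannot parse formula: ", text)
  elements <- ms_table("elements")
  out <- integer(0)
  for (tok in toks) {
    sym <- sub("[0-9]*$", "", tok)
    cnt <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (!sym %in% elements$symbol) stop("unknown element symbol: ", sym)
    if (n <= 0) stop("zero/negative count for element ", sym)
    out[sym] <- (if (sym %in% names(out)) out[[sym]] else 0L) + n
  }
  out
}

#' Total electron count of a formula
#'
#' Sum of atomic numbers times counts, e.g. `"C12H25"` has
#' 12*6 + 25*1 = 97 electrons.
#'
#' @param formula a formula string or a named count vector from
#'   [parse_chemical_formula()].
#' @return number of electrons.
#' @export
electron_count <- function(formula) {
  counts <- if (is.character(formula)) parse_chemical_formula(formula) else formula
  elements <- ms_table("elements")
  z <- setNames(elements$z, elements$symbol)
  unknown <- setdiff(names(counts), names(z))
  if (length(unknown)) stop("unknown element symbol: ", unknown[1])
  sum(z[names(counts)] * as.numeric(counts))
}
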