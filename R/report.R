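#' A priori information record
#'
#' The record that drives modeling-path selection: protein sequence and/or
#' atomic model, detergent head/tail chemical formulae, optional direct
#' electron densities, and the oligomeric symmetry order.
#'
#' @param sequence optional one-letter amino-acid string.
#' @param atoms optional [atom_set()].
#' @param head_formula,tail_formula optional formula strings.
#' @param density_protein,density_head,density_tail,density_buffer optional
#'   electron densities (e-/A^3, in (0, 2)).
#' @param symmetry_order Pn symmetry order (>= 1, default 1).
#' @param head_volume optional head-group volume override (A^3).
#' @return object of class `apriori_info`.
#' @export
apriori_info <- function(sequence = NULL, atoms = NULL,
                         head_formula = NULL, tail_formula = NULL,
                         density_protein = NULL, density_head = NULL,
                         density_tail = NULL, density_buffer = NULL,
                         symmetry_order = 1, head_volume = NULL) {
  for (d in list(density_protein, density_head, density_tail, density_buffer))
    if (!is.null(d) && (d <= 0 || d >= 2))
      stop("electron densities must lie in (0, 2) e-/A^3")
  if (symmetry_order < 1) stop("symmetry_order must be >= 1")
  for (f in list(head_formula, tail_formula))
    if (!is.null(f)) parse_chemical_formula(f)   # validates symbols
  structure(list(sequence = sequence, atoms = atoms,
                 head_formula = head_formula, tail_formula = tail_formula,
                 density_protein = density_protein,
                 density_head = density_head,
                 density_tail = density_tail,
                 density_buffer = density_buffer,
                 symmetry_order = as.integer(symmetry_order),
                 head_volume = head_volume),
            class = "apriori_info")
}

#' Read an a priori record from JSON
#'
#' Keys mirror the [apriori_info()] fields; `atoms` and `sequence` may be
#' given inline or as `atoms_file` (PDB) / `sequence_file` (FASTA) paths
#' resolved relative to the JSON file.
#'
#' @param path JSON file.
#' @return an [apriori_info()].
#' @export
read_apriori <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(path)
  atoms <- NULL
  if (!is.null(j$atoms_file))
    atoms <- read_atoms(file.path(base, j$atoms_file))
  sequence <- j$sequence
  if (is.null(sequence) && !is.null(j$sequence_file))
    sequence <- read_sequence(file.path(base, j$sequence_file))
  apriori_info(sequence = sequence, atoms = atoms,
               head_formula = j$head_formula, tail_formula = j$tail_formula,
               density_protein = j$density_protein,
               density_head = j$density_head,
               density_tail = j$density_tail,
               density_buffer = j$density_buffer,
               symmetry_order = j$symmetry_order %||% 1,
               head_volume = j$head_volume)
}

warning_messages <- c(
  K_LOW_QUALITY = "data quality is low (K >= 30%)",
  K_CAUTION = "data quality requires caution (10% <= K < 30%)",
  FIT_POOR_CHI2 = "model fit is poor (chi2 > 2.0)",
  GUINIER_FAIL = "Guinier fit failed on the subtracted curve",
  SIGMA_FILLED = "uncertainty column was missing and has been synthesized",
  THICKNESS_CLAMPED = "transmembrane thickness clamped at 45 A",
  HEAD_VOLUME_ESTIMATED = "head volume estimated from electron count",
  PROTEIN_DENSITY_DEFAULT = "protein density defaulted to 0.42 e-/A^3",
  UNUSUAL_CONTRAST_SIGNS = "contrast signs differ from the maltoside/water pattern",
  EMPTY_MICELLE_HINT = "hollow single-phase model: possible empty detergent micelle",
  STAGE_FAILED = "a pipeline stage failed for this peak")

make_warning <- function(code, detail = NULL) {
  msg <- warning_messages[[code]] %||% code
  list(code = code, message = if (is.null(detail)) msg
       else paste0(msg, ": ", detail))
}

#' Assemble a summary report
#'
#' @param peaks list of per-peak records (frame ranges, quality, overall
#'   parameters, chosen path, model fit, warnings).
#' @param meta named list of run metadata (seed, config echoes, ...).
#' @return object of class `summary_report`.
#' @export
summary_report <- function(peaks = list(), meta = list()) {
  structure(list(peaks = peaks, meta = meta), class = "summary_report")
}

#' Write a summary report as XML and JSON twins
#'
#' Writes `<path>.xml` and `<path>.json` with identical content; the JSON
#' twin round-trips through [read_summary_json()]. Model files are
#' referenced by relative path.
#'
#' @param report a [summary_report()].
#' @param path destination path without extension.
#' @return invisibly, the two file paths.
#' @export
write_summary <- function(report, path) {
  jd <- list(meta = report$meta, peaks = report$peaks)
  json_path <- paste0(path, ".json")
  jsonlite::write_json(jd, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  doc <- xml2::xml_new_root("sec_saxs_summary")
  meta_node <- xml2::xml_add_child(doc, "meta")
  for (nm in names(report$meta)) {
    v <- report$meta[[nm]]
    if (is.atomic(v) && length(v) == 1)
      xml2::xml_add_child(meta_node, nm, as.character(v))
  }
  add_rec <- function(node, x) {
    for (nm in names(x)) {
      v <- x[[nm]]
      if (is.null(v)) next
      ch <- xml2::xml_add_child(node, nm)
      if (is.list(v)) add_rec(ch, v)
      else xml2::xml_set_text(ch, paste(format(v, digits = 10), collapse = " "))
    }
  }
  for (i in seq_along(report$peaks)) {
    pk <- xml2::xml_add_child(doc, "peak", id = as.character(i))
    add_rec(pk, report$peaks[[i]])
  }
  xml_path <- paste0(path, ".xml")
  xml2::write_xml(doc, xml_path)
  invisible(c(xml = xml_path, json = json_path))
}

#' Read the JSON twin of a summary report
#' @param path the `.json` file written by [write_summary()].
#' @return a [summary_report()].
#' @export
read_summary_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  simplify <- function(x) {
    if (!is.list(x)) return(x)
    nm <- names(x)
    if (is.null(nm) && length(x) > 0 &&
        all(vapply(x, function(e) is.atomic(e) && length(e) == 1, logical(1))))
      return(unlist(x))
    lapply(x, simplify)
  }
  summary_report(peaks = simplify(j$peaks), meta = simplify(j$meta))
}

#' Bundle frame profiles into a single archive
#'
#' Writes every frame as a 3-column `.dat` plus a JSON manifest and packs
#' them into one gzip tar archive: the single-file frame bundle the
#' pipeline reports alongside the summary.
#'
#' @param series a [frame_series()].
#' @param path destination `.tar.gz`.
#' @return invisibly, `path`.
#' @export
bundle_frames <- function(series, path) {
  tmp <- tempfile("bundle")
  dir.create(tmp)
  old <- getwd()
  on.exit({ setwd(old); unlink(tmp, recursive = TRUE) })
  for (j in seq_len(series$frame_count))
    write_profile(series_frame(series, j),
                  file.path(tmp, sprintf("frame_%05d.dat", j)))
  jsonlite::write_json(
    list(frames = series$frame_count, points = length(series$s),
         s_min = min(series$s), s_max = max(series$s)),
    file.path(tmp, "manifest.json"), auto_unbox = TRUE)
  dest <- if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(old, path)
  setwd(tmp)
  tar(dest, files = ".", compression = "gzip", tar = "internal")
  invisible(path)
}
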