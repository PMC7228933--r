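#' Pipeline configuration
#'
#' One layered place for every tunable of the end-to-end run; defaults
#' reflect routine beamline operation, and smaller grids can be set for
#' quick runs.
#'
#' @param k_reliable,k_low K thresholds (percent) for the reliable /
#'   low-quality verdicts.
#' @param chi2_flag model-fit chi-square above which the poor-fit warning
#'   fires.
#' @param smax_ceiling ceiling for the automatic s_max (A^-1).
#' @param beads_per_diameter three-phase grid resolution.
#' @param single_beads_per_diameter single-phase grid resolution.
#' @param runs number of independent single-phase reconstructions fed to
#'   the consensus (default 10).
#' @param seed master RNG seed.
#' @param anneal an [anneal_config()].
#' @param corona_steps corona grid nodes per axis.
#' @param corona_spacing corona lattice spacing (A).
#' @param proceed_on_low_quality keep modeling when K >= 30% (warning
#'   only) or stop for that peak.
#' @return list of class `ampp_config`.
#' @export
ampp_config <- function(k_reliable = 10, k_low = 30, chi2_flag = 2,
                        smax_ceiling = 0.10, beads_per_diameter = 40,
                        single_beads_per_diameter = 24, runs = 10,
                        seed = 1, anneal = anneal_config(seed = seed),
                        corona_steps = 7, corona_spacing = 3,
                        proceed_on_low_quality = TRUE) {
  structure(as.list(environment()), class = "ampp_config")
}

#' Select the modeling path from the a priori record
#'
#' Deterministic decision engine: the hybrid path needs an atomic model
#' plus both detergent formulae; the multi-phase ab initio path needs both
#' detergent formulae (mandatory detergent chemistry) plus protein density
#' information (sequence or a direct density); anything less falls back to
#' single-phase ab initio shape determination.
#'
#' @param apriori an [apriori_info()] record.
#' @return list of class `path_choice`: `path` (one of `hybrid`,
#'   `multiphase_abinitio`, `singlephase_abinitio`) and `justification`
#'   listing every field consulted.
#' @export
select_path <- function(apriori) {
  has <- list(
    atoms = !is.null(apriori$atoms),
    head_formula = !is.null(apriori$head_formula),
    tail_formula = !is.null(apriori$tail_formula),
    sequence = !is.null(apriori$sequence),
    density_protein = !is.null(apriori$density_protein))
  formulae <- has$head_formula && has$tail_formula
  path <- if (has$atoms && formulae) "hybrid"
  else if (formulae && (has$sequence || has$density_protein)) "multiphase_abinitio"
  else "singlephase_abinitio"
  just <- vapply(names(has), function(nm)
    sprintf("%s: %s", nm, if (has[[nm]]) "present" else "absent"), character(1))
  structure(list(path = path, justification = unname(just)),
            class = "path_choice")
}

#' @export
print.path_choice <- function(x, ...) {
  cat("modeling path:", x$path, "\n")
  cat(paste(" -", x$justification, collapse = "\n"), "\n")
  invisible(x)
}

model_one_peak <- function(subtracted, apriori, config, out_dir, peak_id) {
  warnings <- list()
  note <- function(code, detail = NULL)
    warnings[[length(warnings) + 1]] <<- make_warning(code, detail)
  gf <- guinier_fit(subtracted)
  pr <- pr_transform(subtracted)
  pv <- porod_volume_mw(subtracted, gf$I0, gf$Rg)
  if (pr$Dmax < 2 * gf$Rg * sqrt(5 / 3) * 0.8) note("STAGE_FAILED",
    "Dmax below the Guinier sanity bound; flagged, not fatal")
  choice <- select_path(apriori)
  spec <- if (!is.null(apriori$tail_formula) && !is.null(apriori$head_formula))
    detergent_spec(apriori$tail_formula, apriori$head_formula,
                   head_volume = apriori$head_volume) else NULL
  model_info <- list()
  model_chi2 <- NA_real_
  model_file <- NULL
  smax <- first_minimum_smax(subtracted, ceiling = config$smax_ceiling)
  if (choice$path == "hybrid") {
    contrasts <- phase_densities(apriori, spec)
    fit <- fit_corona(apriori$atoms, subtracted, spec, contrasts,
                      n_steps = config$corona_steps,
                      spacing = config$corona_spacing)
    model_chi2 <- fit$chi2
    for (w in fit$warnings) note(w)
    model_info <- list(engine = "corona_fit", geometry = fit$geometry)
    if (!is.null(out_dir)) {
      model_file <- sprintf("peak%d_corona.pdb", peak_id)
      write_bead_pdb(fit$body, file.path(out_dir, model_file))
    }
  } else if (choice$path == "multiphase_abinitio") {
    contrasts <- phase_densities(apriori, spec)
    for (w in contrasts$flags) note(w)
    vol <- build_search_volume(pr$Dmax, spec,
                               beads_per_diameter = config$beads_per_diameter,
                               symmetry_order = apriori$symmetry_order,
                               mw_da = if (!is.null(apriori$sequence))
                                 sequence_composition(apriori$sequence)$mw else NULL)
    expd <- expected_phase_metrics(vol, pv$V_porod)
    cfg <- config$anneal; cfg$seed <- config$seed
    model <- anneal_multiphase(vol, subtracted, contrasts, expd, cfg)
    model_chi2 <- model$chi2
    if (model_chi2 > config$chi2_flag) note("FIT_POOR_CHI2")
    model_info <- list(engine = "multiphase",
                       phase_counts = as.list(table(model$phase)))
    if (!is.null(out_dir)) {
      model_file <- sprintf("peak%d_multiphase.pdb", peak_id)
      write_bead_pdb(model, file.path(out_dir, model_file))
    }
  } else {
    runs <- lapply(seq_len(config$runs), function(k) {
      cfg <- config$anneal; cfg$seed <- config$seed * 1000 + k
      anneal_singlephase(subtracted, smax, pr$Dmax,
                         symmetry_order = apriori$symmetry_order,
                         config = cfg,
                         beads_per_diameter = config$single_beads_per_diameter,
                         v_porod = pv$V_porod)
    })
    cfg <- config$anneal; cfg$seed <- config$seed * 1000
    model <- consensus_model(runs, subtracted, smax, config = cfg)
    model_chi2 <- model$chi2
    if (model_chi2 > config$chi2_flag) note("FIT_POOR_CHI2")
    hollow <- hollowness(model)
    if (is.finite(hollow) && hollow < 0.3) note("EMPTY_MICELLE_HINT")
    model_info <- list(engine = "singlephase_consensus",
                       nsd_mean = model$provenance$nsd_mean,
                       nsd_sd = model$provenance$nsd_sd,
                       runs = config$runs)
    if (!is.null(out_dir)) {
      model_file <- sprintf("peak%d_singlephase.pdb", peak_id)
      write_bead_pdb(model, file.path(out_dir, model_file))
    }
  }
  list(guinier = gf, pr = pr, porod = pv, choice = choice, s_max = smax,
       model_chi2 = model_chi2, model_info = model_info,
       model_file = model_file, warnings = warnings)
}

#' Central-to-shell occupancy ratio of a single-phase model
#'
#' The hollowness signature used for the empty-micelle hint: occupancy of
#' the central region (radius < 40% of the particle extent) divided by the
#' occupancy of the outer shell. Values below ~0.3 indicate a hollow
#' reconstruction.
#'
#' @param model a single-phase `bead_model`.
#' @return ratio in [0, Inf]; NA when undefined.
#' @export
hollowness <- function(model) {
  occ <- model$phase != "solvent"
  r <- sqrt(rowSums(model$xyz^2))
  rmax <- max(r[occ])
  core <- r < 0.4 * rmax
  shell <- r >= 0.4 * rmax & r <= rmax
  if (!any(core) || !any(shell)) return(NA_real_)
  mean(occ[core]) / max(mean(occ[shell]), 1e-12)
}

#' Run the full SEC-SAXS pipeline
#'
#' Executes the workflow end to end: load frames, build the chromatogram,
#' detect buffer and sample regions, average and subtract per peak, score
#' data quality with K, compute the overall parameters, select the
#' modeling path from the a priori record, run the chosen engine, and
#' assemble the summary report (XML + JSON twins) plus the frame bundle.
#' A failing stage is recorded in the report for its peak and the
#' remaining peaks continue.
#'
#' @param frames a [frame_series()] or a directory of frame `.dat` files.
#' @param apriori an [apriori_info()] record (may be empty).
#' @param config an [ampp_config()].
#' @param out_dir optional output directory (subtracted curves,
#'   chromatogram TSV, models, summary, bundle).
#' @return a [summary_report()].
#' @export
run_pipeline <- function(frames, apriori = apriori_info(),
                         config = ampp_config(), out_dir = NULL) {
  series <- if (inherits(frames, "frame_series")) frames
  else read_frame_series(frames)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  elution <- build_elution_profile(series)
  regions <- detect_regions(series)
  if (!is.null(out_dir)) {
    write.table(data.frame(frame = seq_along(elution) - 1L,
                           integral_intensity = elution),
                file.path(out_dir, "chromatogram.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    bundle_frames(series, file.path(out_dir, "frames.tar.gz"))
  }
  peaks <- list()
  for (i in seq_along(regions$sample_ranges)) {
    sr <- regions$sample_ranges[[i]]
    br <- regions$buffer_ranges[[1]]
    rec <- list(buffer_range = br, sample_range = sr,
                peak_frame = regions$peak_frames[i])
    warnings <- list()
    res <- tryCatch({
      subtracted <- scale_and_subtract(series, sr, br)
      q <- quality_K(series, sr, subtracted)
      for (w in q$warnings) warnings[[length(warnings) + 1]] <- make_warning(w)
      rec$quality <- list(K = q$K, c_v_aver = q$c_v_aver,
                          mean_chi2 = q$mean_chi2, verdict = q$verdict)
      if (!is.null(out_dir))
        write_profile(subtracted,
                      file.path(out_dir, sprintf("peak%d_subtracted.dat", i)))
      proceed <- config$proceed_on_low_quality || q$verdict != "low_quality"
      if (proceed) {
        mod <- model_one_peak(subtracted, apriori, config, out_dir, i)
        warnings <- c(warnings, mod$warnings)
        rec$overall <- list(Rg = mod$guinier$Rg, I0 = mod$guinier$I0,
                            Rg_real = mod$pr$Rg_real, Dmax = mod$pr$Dmax,
                            V_porod = mod$porod$V_porod,
                            MW_kda = mod$porod$MW_kda,
                            s_max = mod$s_max)
        rec$path <- mod$choice$path
        rec$justification <- mod$choice$justification
        rec$model <- c(list(chi2 = mod$model_chi2, file = mod$model_file),
                       mod$model_info)
      }
      rec
    }, error = function(e) {
      warnings[[length(warnings) + 1]] <<- make_warning("STAGE_FAILED",
                                                        conditionMessage(e))
      rec
    })
    res$warnings <- warnings
    peaks[[i]] <- res
  }
  report <- summary_report(
    peaks = peaks,
    meta = list(n_frames = series$frame_count, n_points = length(series$s),
                seed = config$seed,
                package = "memsaxs",
                version = as.character(utils::packageVersion("memsaxs"))))
  if (!is.null(out_dir))
    write_summary(report, file.path(out_dir, "summary"))
  report
}

#' @export
print.summary_report <- function(x, ...) {
  cat(sprintf("SEC-SAXS summary: %d peak(s)\n", length(x$peaks)))
  for (i in seq_along(x$peaks)) {
    p <- x$peaks[[i]]
    cat(sprintf(" peak %d: frames [%s), K = %s (%s), path = %s, model chi2 = %s\n",
                i, paste(p$sample_range, collapse = ", "),
                if (!is.null(p$quality)) sprintf("%.1f%%", p$quality$K) else "NA",
                p$quality$verdict %||% "?", p$path %||% "-",
                if (!is.null(p$model)) sprintf("%.2f", p$model$chi2) else "-"))
    for (w in p$warnings) cat("   warning:", w$code, "-", w$message, "\n")
  }
  invisible(x)
}
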