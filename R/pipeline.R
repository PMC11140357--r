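#' Quantify donor chimerism from one gel lane
#'
#' Runs the full densitometry chain on a single lane: profile extraction,
#' baseline subtraction, peak detection, valley-rule area integration,
#' fragment sizing, allele labelling, and the chimerism computation.
#'
#' @param image A `gel_image`.
#' @param lane 1-based lane index.
#' @param call The [classify_alleles()] result for the analysed locus.
#' @param locus The [str_locus()]; defaults to the panel locus in `call`.
#' @param calibration A `size_calibration` (from [calibrate_sizes()]) or a
#'   `gel_render_spec` used as exact calibration; defaults to the image's
#'   own render spec when the image is synthetic.
#' @param baseline_window,min_prominence_frac,min_separation_px Densitometry
#'   thresholds; see [subtract_baseline()] and [detect_peaks()].
#' @param tolerance_bp Allele-matching tolerance; see
#'   [match_peaks_to_alleles()].
#' @param mode `"simple"` (simple-complement, the default) or `"paired"`.
#' @param integration `"valley"` or `"gaussian"`; see [integrate_peaks()].
#' @return A `chimerism_result`; its `peaks` field holds the labelled peak
#'   table.
#' @examples
#' call <- classify_alleles(genotype("D5S818", c(12, 12)),
#'                          genotype("D5S818", c(10, 12)))
#' scene <- make_chimera_lane(call, 0.606, gel_render_spec(noise_sd = 0))
#' quantify_lane(scene$image, 1, call)
#' @export
quantify_lane <- function(image, lane, call,
                          locus = panel_locus(default_panel(), call$locus),
                          calibration = image$spec,
                          baseline_window = 10L,
                          min_prominence_frac = 0.02,
                          min_separation_px = 4L,
                          tolerance_bp = locus$repeat_unit_bp / 2,
                          mode = c("simple", "paired"),
                          integration = c("valley", "gaussian")) {
  mode <- match.arg(mode)
  integration <- match.arg(integration)
  if (is.null(calibration))
    stop("no size calibration: supply one from calibrate_sizes() or a render spec")
  prof <- extract_lane_profile(image, lane)
  prof <- subtract_baseline(prof, baseline_window)
  pk <- detect_peaks(prof, min_prominence_frac, min_separation_px)
  if (nrow(pk) == 0L) stop("no peaks detected in lane ", lane)
  pk <- integrate_peaks(prof, pk, method = integration)
  pk <- assign_peak_sizes(pk, calibration)
  pk <- match_peaks_to_alleles(pk, call, locus, tolerance_bp)
  if (mode == "simple") donor_chimerism_simple(pk, locus = call$locus)
  else donor_chimerism_paired(pk, locus = call$locus, call = call)
}

#' Read a pipeline run configuration
#'
#' YAML configuration with fields: `genotypes` (TSV path), `image` (path)
#' plus `lanes` (list of `x_start`/`x_end`), `polarity`, `bit_depth` — or
#' `profile` (TSV path) instead of an image; `samples` (list of
#' `lane`/`sample_id`/`pair_id` and optional `locus`); sizing via `ladder`
#' (`lane` + `sizes`) or `migration` (`a`, `b`); optional `thresholds`
#' (`baseline_window`, `min_prominence_frac`, `min_separation_px`,
#' `tolerance_bp`); `mode` (`simple`/`paired`); `out_dir`; `seed`.
#'
#' @param path YAML file path.
#' @return Named list (class `strchim_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "strchim_config")
}

cfg_get <- function(cfg, name, default = NULL) {
  if (!is.null(cfg[[name]])) cfg[[name]] else default
}

#' Run the full genotype-to-report pipeline
#'
#' Orchestrates: genotype classification for each configured sample's pair,
#' informative-locus selection, lane densitometry, allele labelling,
#' chimerism computation, and report writing. Every stage logs its
#' parameters; the run is deterministic given the configuration and inputs.
#'
#' @param config A list or `strchim_config` (see [read_run_config()]), or a
#'   YAML path.
#' @param log Function receiving log lines (default writes to `stderr`).
#' @return Invisibly, a list with `status` (0 success, 2 invalid
#'   configuration, 3 no informative locus for a sample, 4 densitometry
#'   failure), `report` (`data.frame`), and the written file paths.
#' @export
run_pipeline <- function(config, log = function(msg) message(msg)) {
  if (is.character(config)) config <- read_run_config(config)
  status <- 0L

  fail <- function(code, msg) {
    log(paste0("[error] ", msg))
    return(invisible(list(status = code, report = NULL, files = character(0))))
  }
  for (field in c("genotypes", "samples", "out_dir"))
    if (is.null(config[[field]]))
      return(fail(2L, paste0("config: missing required field '", field, "'")))
  if (is.null(config$image) && is.null(config$profile))
    return(fail(2L, "config: need either 'image' (+ lanes) or 'profile'"))
  mode <- cfg_get(config, "mode", "simple")
  if (!mode %in% c("simple", "paired"))
    return(fail(2L, paste0("config: unknown mode '", mode, "'")))
  if (!file.exists(config$genotypes))
    return(fail(2L, paste0("config: genotype table not found: ", config$genotypes)))

  th <- cfg_get(config, "thresholds", list())
  baseline_window <- cfg_get(th, "baseline_window", 10L)
  min_prom <- cfg_get(th, "min_prominence_frac", 0.02)
  min_sep <- cfg_get(th, "min_separation_px", 4L)

  log(paste0("[genotypes] reading ", config$genotypes))
  cohort <- read_genotypes(config$genotypes)
  names(cohort) <- vapply(cohort, `[[`, character(1), "pair_id")
  panel <- default_panel()

  image <- NULL
  if (!is.null(config$image)) {
    if (!file.exists(config$image))
      return(fail(2L, paste0("config: image not found: ", config$image)))
    lanes <- do.call(rbind, lapply(config$lanes, as.data.frame))
    log(paste0("[image] reading ", config$image, " (", nrow(lanes), " lanes)"))
    image <- read_gel_image(config$image, lanes,
                            polarity = cfg_get(config, "polarity", "dark"),
                            bit_depth = cfg_get(config, "bit_depth", 8L))
  }

  calibration <- NULL
  if (!is.null(config$migration)) {
    calibration <- structure(
      list(a = config$migration$a, b = config$migration$b,
           residual_rms_px = 0, n_bands = 0L),
      class = "size_calibration")
    log(sprintf("[sizing] migration model a=%.3f b=%.3f", calibration$a,
                calibration$b))
  } else if (!is.null(config$ladder)) {
    lp <- subtract_baseline(extract_lane_profile(image, config$ladder$lane),
                            baseline_window)
    calibration <- calibrate_sizes(lp, as.numeric(config$ladder$sizes),
                                   min_prominence_frac = min_prom,
                                   min_separation_px = min_sep)
    log(sprintf("[sizing] ladder fit a=%.3f b=%.3f rms=%.3g px",
                calibration$a, calibration$b, calibration$residual_rms_px))
  } else {
    return(fail(2L, "config: need 'ladder' or 'migration' for fragment sizing"))
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  results <- list()
  for (s in config$samples) {
    sid <- cfg_get(s, "sample_id", paste0("lane", s$lane))
    pair <- cohort[[s$pair_id]]
    if (is.null(pair))
      return(fail(2L, paste0("config: pair '", s$pair_id, "' not in genotype table")))
    calls <- informative_loci(pair)
    calls <- Filter(function(cl) length(cl$recipient_exclusive) > 0, calls)
    if (!is.null(s$locus))
      calls <- Filter(function(cl) cl$locus == s$locus, calls)
    if (length(calls) == 0L) {
      log(paste0("[chimerism] ", sid, ": no informative locus with ",
                 "recipient-exclusive signal for pair ", s$pair_id))
      rows[[sid]] <- data.frame(sample_id = sid, locus = NA, mode = mode,
                                donor_percent = NA, recipient_percent = NA,
                                flag = "not informative")
      status <- 3L
      next
    }
    call <- calls[[1]]
    log(paste0("[densitometry] ", sid, ": lane ", s$lane, ", locus ",
               call$locus))
    res <- tryCatch({
      if (!is.null(config$profile)) {
        prof <- subtract_baseline(read_profile(config$profile, lane = s$lane),
                                  baseline_window)
        pk <- detect_peaks(prof, min_prom, min_sep)
        if (nrow(pk) == 0L) stop("no peaks detected")
        pk <- integrate_peaks(prof, pk)
        pk <- assign_peak_sizes(pk, calibration)
        pk <- match_peaks_to_alleles(pk, call, panel_locus(panel, call$locus))
        if (mode == "simple") donor_chimerism_simple(pk, locus = call$locus)
        else donor_chimerism_paired(pk, locus = call$locus, call = call)
      } else {
        quantify_lane(image, s$lane, call,
                      locus = panel_locus(panel, call$locus),
                      calibration = calibration,
                      baseline_window = baseline_window,
                      min_prominence_frac = min_prom,
                      min_separation_px = min_sep, mode = mode)
      }
    }, error = function(e) e)
    if (inherits(res, "error"))
      return(fail(4L, paste0("densitometry stage, sample ", sid, ": ",
                             conditionMessage(res))))
    results[[sid]] <- res
    rows[[sid]] <- data.frame(sample_id = sid, locus = res$locus, mode = res$mode,
                              donor_percent = sprintf("%.1f", res$donor_percent),
                              recipient_percent = sprintf("%.1f", res$recipient_percent),
                              flag = paste(res$flags, collapse = ";"))
    log(sprintf("[chimerism] %s: donor %.1f%% (%s, locus %s)", sid,
                res$donor_percent, res$mode, res$locus))
  }

  report <- do.call(rbind, rows)
  tsv <- file.path(config$out_dir, "chimerism_report.tsv")
  con <- file(tsv, "w")
  writeLines(c(
    sprintf("# mode = %s", mode),
    sprintf("# baseline_window = %d", baseline_window),
    sprintf("# min_prominence_frac = %g", min_prom),
    sprintf("# min_separation_px = %d", min_sep),
    sprintf("# sizing = a=%.6g b=%.6g", calibration$a, calibration$b),
    sprintf("# seed = %s", cfg_get(config, "seed", "none"))), con)
  utils::write.table(report, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  json <- file.path(config$out_dir, "chimerism_report.json")
  if (length(results) > 0)
    write_chimerism_report(results, file.path(config$out_dir, "per_locus.tsv"),
                           path_json = json,
                           sample_id = paste(names(results), collapse = ","),
                           params = list(mode = mode,
                                         baseline_window = baseline_window,
                                         min_prominence_frac = min_prom,
                                         min_separation_px = min_sep))
  log(paste0("[report] wrote ", tsv))
  invisible(list(status = status, report = report,
                 files = c(tsv, if (length(results) > 0) json)))
}

#' Write demonstration fixtures
#'
#' Writes the 20-pair genotype cohort (TSV) plus two demo gel scenes — a
#' two-band lane with a homozygous donor (shared upper band,
#' recipient-exclusive lower band) and a three-band lane with a
#' recipient-exclusive middle allele — each as PNG with its ground-truth
#' TSV.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer RNG seed.
#' @return Invisibly, the written paths.
#' @export
write_demo_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  cohort <- make_table1_fixture(seed)
  p <- file.path(out_dir, "cohort_genotypes.tsv")
  write_genotypes(cohort, p)
  paths <- c(paths, p)

  scenes <- list(
    two_band = list(
      call = classify_alleles(genotype("D5S818", c(12, 12)),
                              genotype("D5S818", c(10, 12))),
      fraction = 0.606),
    three_band = list(
      call = classify_alleles(genotype("D3S1358", c(13, 16)),
                              genotype("D3S1358", c(14, 16))),
      fraction = 0.794)
  )
  for (nm in names(scenes)) {
    sc <- scenes[[nm]]
    spec <- gel_render_spec(seed = seed)
    scene <- make_chimera_lane(sc$call, sc$fraction, spec)
    img <- file.path(out_dir, paste0(nm, ".png"))
    write_gel_image(scene$image, img)
    gt <- file.path(out_dir, paste0(nm, "_truth.tsv"))
    utils::write.table(scene$truth, gt, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, img, gt)
  }
  invisible(paths)
}
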