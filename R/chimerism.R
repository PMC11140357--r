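new_chimerism_result <- function(locus, mode, recipient_percent, peaks,
                                 complete_threshold = 95) {
  stopifnot(recipient_percent >= 0, recipient_percent <= 100)
  donor_percent <- 100 - recipient_percent
  structure(
    list(locus = locus, mode = mode,
         donor_percent = donor_percent, recipient_percent = recipient_percent,
         peaks = peaks,
         flags = c(
           if (donor_percent >= complete_threshold) "complete_chimerism"
           else "mixed_chimerism",
           if (recipient_percent > 0) "recipient_signal_present"
         ),
         complete_threshold = complete_threshold),
    class = "chimerism_result")
}

#' @export
print.chimerism_result <- function(x, ...) {
  cat(sprintf("<chimerism_result> %s [%s]: donor %.1f%%, recipient %.1f%% (%s)\n",
              x$locus, x$mode, x$donor_percent, x$recipient_percent,
              paste(x$flags, collapse = ", ")))
  invisible(x)
}

check_labelled <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  if (is.null(peaks$label) || is.null(peaks$area))
    stop("peaks must carry 'label' and 'area' columns (integrated + labelled)")
  peaks[peaks$label %in% c("recipient_exclusive", "donor_exclusive", "shared"), ,
        drop = FALSE]
}

#' Donor chimerism, simple-complement mode
#'
#' The standard gel-densitometry arithmetic: the recipient percentage is the
#' recipient-exclusive peaks' share of the total labelled peak area at the
#' locus (shared and donor-exclusive peaks included in the denominator), and
#' the donor percentage is its complement to 100. Unassigned peaks are
#' excluded from the normalization. No dosage correction is applied: areas
#' are read as-is, so a shared band carrying donor and recipient copies
#' counts once, at its full area.
#'
#' @param peaks Integrated, labelled peak table (see
#'   [match_peaks_to_alleles()]); must contain at least one
#'   `recipient_exclusive` peak label.
#' @param locus Locus name recorded in the result (default taken from a
#'   `locus` column or `NA`).
#' @param complete_threshold Donor percentage at or above which the result
#'   is flagged complete chimerism; default 95 — a reporting convention,
#'   not a quantity estimated by this method.
#' @return A `chimerism_result`: `donor_percent`, `recipient_percent`
#'   (summing to 100), contributing peaks, interpretation flags.
#' @examples
#' pk <- data.frame(peak = 1:2, area = c(60.6, 39.4),
#'                  label = c("shared", "recipient_exclusive"))
#' donor_chimerism_simple(pk, locus = "D5S818")
#' @export
donor_chimerism_simple <- function(peaks, locus = NA_character_,
                                   complete_threshold = 95) {
  lp <- check_labelled(peaks)
  if (!any(lp$label == "recipient_exclusive"))
    stop("locus not informative for recipient signal: ",
         "no peak labelled recipient_exclusive")
  total <- sum(lp$area)
  if (total <= 0) stop("total labelled peak area is zero")
  rec <- 100 * sum(lp$area[lp$label == "recipient_exclusive"]) / total
  new_chimerism_result(locus, "simple_complement", rec, lp, complete_threshold)
}

#' Donor chimerism, paired-informative mode
#'
#' Alternative estimator for fully informative loci: the recipient
#' percentage is computed from the exclusive peaks only —
#' recipient-exclusive area over the sum of recipient- and donor-exclusive
#' areas — with shared peaks excluded. With `dosage_correct = TRUE`, each
#' exclusive area is divided by the allele's copy number in its carrier
#' before the ratio, correcting for homozygous bands carrying two copies.
#'
#' @param peaks Integrated, labelled peak table with at least one
#'   `recipient_exclusive` and one `donor_exclusive` label.
#' @param call Optional [classify_alleles()] result, required for
#'   `dosage_correct = TRUE` (supplies the allele dosages).
#' @param dosage_correct Divide exclusive areas by allele copy number.
#' @inheritParams donor_chimerism_simple
#' @return A `chimerism_result`.
#' @export
donor_chimerism_paired <- function(peaks, locus = NA_character_, call = NULL,
                                   dosage_correct = FALSE,
                                   complete_threshold = 95) {
  lp <- check_labelled(peaks)
  r <- lp$label == "recipient_exclusive"
  d <- lp$label == "donor_exclusive"
  if (!any(r) || !any(d))
    stop("paired mode needs both recipient- and donor-exclusive peaks; got ",
         sum(r), " recipient-exclusive and ", sum(d), " donor-exclusive")
  area_r <- lp$area[r]
  area_d <- lp$area[d]
  if (dosage_correct) {
    if (is.null(call) || is.null(lp$allele))
      stop("dosage correction needs the informative call and peak alleles")
    area_r <- area_r / allele_dosage(call$recipient)[as.character(lp$allele[r])]
    area_d <- area_d / allele_dosage(call$donor)[as.character(lp$allele[d])]
  }
  tot <- sum(area_r) + sum(area_d)
  if (tot <= 0) stop("total exclusive peak area is zero")
  rec <- 100 * sum(area_r) / tot
  new_chimerism_result(locus, "paired_informative", rec, lp, complete_threshold)
}

#' Aggregate chimerism results
#'
#' Unweighted summary across loci or samples: arithmetic mean and range of
#' the donor percentages, plus the per-result table. Gel densitometry
#' typically quantifies a single informative locus per sample, so multi-locus
#' aggregation is an extension and the per-locus values are always reported
#' alongside.
#'
#' @param results List of `chimerism_result` objects (>= 1).
#' @return List with `mean_donor_percent`, `range_donor_percent`
#'   (`c(min, max)`) and `per_locus` (`data.frame`).
#' @export
aggregate_chimerism <- function(results) {
  if (length(results) == 0L) stop("no chimerism results to aggregate")
  stopifnot(all(vapply(results, inherits, logical(1), "chimerism_result")))
  dp <- vapply(results, `[[`, numeric(1), "donor_percent")
  list(
    mean_donor_percent = mean(dp),
    range_donor_percent = range(dp),
    per_locus = data.frame(
      locus = vapply(results, `[[`, character(1), "locus"),
      mode = vapply(results, `[[`, character(1), "mode"),
      donor_percent = dp,
      recipient_percent = vapply(results, `[[`, numeric(1), "recipient_percent"),
      stringsAsFactors = FALSE)
  )
}

#' Write a chimerism report
#'
#' Writes the result(s) as TSV (one row per locus: sample, locus, mode,
#' donor and recipient percentages to one decimal place) and, optionally, as
#' JSON with the full peak breakdown and the analysis parameters echoed for
#' provenance.
#'
#' @param results List of `chimerism_result` objects.
#' @param path_tsv Output TSV path.
#' @param path_json Optional JSON path.
#' @param sample_id Sample identifier recorded in the report.
#' @param params Optional named list of analysis parameters to echo.
#' @return `path_tsv`, invisibly.
#' @export
write_chimerism_report <- function(results, path_tsv, path_json = NULL,
                                   sample_id = NA_character_, params = NULL) {
  agg <- aggregate_chimerism(results)
  tab <- cbind(sample_id = sample_id, agg$per_locus)
  tab$donor_percent <- sprintf("%.1f", tab$donor_percent)
  tab$recipient_percent <- sprintf("%.1f", tab$recipient_percent)
  con <- file(path_tsv, "w")
  on.exit(close(con))
  if (!is.null(params))
    writeLines(sprintf("# %s = %s", names(params),
                       vapply(params, function(p) paste(format(p), collapse = ","),
                              character(1))), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(sample_id = sample_id, params = params,
           mean_donor_percent = agg$mean_donor_percent,
           results = lapply(results, function(r)
             list(locus = r$locus, mode = r$mode,
                  donor_percent = r$donor_percent,
                  recipient_percent = r$recipient_percent,
                  flags = r$flags,
                  peaks = r$peaks))),
      path_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path_tsv)
}
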