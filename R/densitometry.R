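#' Extract a 1D lane profile from a gel image
#'
#' Averages pixel intensity across the lane's columns, row by row,
#' normalizes polarity so bands are positive excursions regardless of
#' whether they were darker (silver stain) or lighter than the background,
#' and applies a light moving-average denoising along the migration axis
#' (linear, so band areas and their ratios are preserved). Positions are
#' 0-based pixel rows from the well.
#'
#' @param image A `gel_image`.
#' @param lane_index 1-based lane index into the image's lane map.
#' @param smooth_px Half-width of the moving-average denoiser in px
#'   (default 2, i.e. a 5-sample window); 0 disables smoothing.
#' @return An object of class `lane_profile`: list with `intensities`
#'   (numeric vector, one value per row), `lane`, `baselined` flag.
#' @export
extract_lane_profile <- function(image, lane_index, smooth_px = 2L) {
  stopifnot(inherits(image, "gel_image"))
  if (!lane_index %in% image$lanes$lane)
    stop("lane index ", lane_index, " out of range (lanes ",
         min(image$lanes$lane), "-", max(image$lanes$lane), ")")
  lb <- image$lanes[image$lanes$lane == lane_index, ]
  cols <- (lb$x_start + 1):lb$x_end  # 0-based half-open -> 1-based R columns
  prof <- rowMeans(image$pixels[, cols, drop = FALSE])
  maxval <- 2^image$bit_depth - 1
  if (image$polarity == "dark") prof <- maxval - prof
  if (smooth_px > 0) prof <- rolling_mean(prof, smooth_px)
  new_lane_profile(prof, lane = lane_index, baselined = FALSE)
}

new_lane_profile <- function(intensities, lane = NA_integer_, baselined = FALSE) {
  intensities <- as.numeric(intensities)
  if (length(intensities) < 8L) stop("a lane profile needs >= 8 samples")
  if (any(!is.finite(intensities))) stop("lane profile has non-finite values")
  structure(list(intensities = intensities, lane = lane, baselined = baselined),
            class = "lane_profile")
}

#' Construct a lane profile from raw intensities
#'
#' For profiles obtained outside the image reader (e.g. exported by other
#' densitometry software). Values are taken as already polarity-normalized:
#' bands must be positive excursions.
#'
#' @param intensities Numeric vector, position 0-based from the well.
#' @param lane Optional lane index for provenance.
#' @param baselined Set `TRUE` if the baseline is already removed.
#' @return A `lane_profile`.
#' @export
lane_profile <- function(intensities, lane = NA_integer_, baselined = FALSE) {
  new_lane_profile(intensities, lane, baselined)
}

#' @export
print.lane_profile <- function(x, ...) {
  cat(sprintf("<lane_profile> lane %s, %d px, max %.3g%s\n",
              ifelse(is.na(x$lane), "?", x$lane), length(x$intensities),
              max(x$intensities), if (x$baselined) ", baselined" else ""))
  invisible(x)
}

#' Read / write a lane profile as two-column TSV
#'
#' Columns `position_px` (0-based) and `intensity`.
#'
#' @param path TSV path.
#' @param lane Optional lane index for provenance (read only).
#' @return [read_profile()]: a `lane_profile`. [write_profile()]: `path`,
#'   invisibly.
#' @export
read_profile <- function(path, lane = NA_integer_) {
  df <- utils::read.delim(path, comment.char = "#")
  stopifnot(all(c("position_px", "intensity") %in% names(df)))
  df <- df[order(df$position_px), ]
  if (!all(diff(df$position_px) == 1))
    stop("profile positions must be consecutive integer pixels")
  lane_profile(df$intensity, lane = lane)
}

#' @rdname read_profile
#' @param profile A `lane_profile`.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(
    data.frame(position_px = seq_along(profile$intensities) - 1L,
               intensity = profile$intensities),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

rolling_stat <- function(x, half_width, fun) {
  n <- length(x)
  vapply(seq_len(n), function(i)
    fun(x[max(1L, i - half_width):min(n, i + half_width)]), numeric(1))
}

rolling_min <- function(x, half_width) rolling_stat(x, half_width, min)
rolling_max <- function(x, half_width) rolling_stat(x, half_width, max)
rolling_mean <- function(x, half_width) rolling_stat(x, half_width, mean)

#' Subtract the background baseline from a lane profile
#'
#' Morphological baseline: a rolling minimum followed by a rolling maximum
#' of the same half-width (a morphological opening, which reproduces any
#' background feature wider than the window exactly — a linear gradient
#' leaves no residual), lightly smoothed with a rolling mean of half the
#' window. The estimate is then re-centred on the median of the remaining
#' residuals, so that on a noisy profile the baseline passes through the
#' middle of the noise rather than its lower envelope, and subtracted; small
#' negative residuals are clipped to zero. The window must be wider than the
#' bands (several band sigmas) so peaks are not eroded, yet narrower than
#' the background's variation — the smooth vertical gradient typical of
#' photographed silver-stained gels.
#'
#' @param profile A `lane_profile`.
#' @param window_px Rolling-window half-width in px; default 10, several
#'   times the rendered band sigma. Must be >= 3 and less than the profile
#'   length.
#' @return A baselined `lane_profile`.
#' @export
subtract_baseline <- function(profile, window_px = 10L) {
  stopifnot(inherits(profile, "lane_profile"))
  x <- profile$intensities
  n <- length(x)
  if (window_px < 3L || window_px >= n)
    stop("window_px must be >= 3 and < profile length (", n, "), got ",
         window_px)
  base <- rolling_mean(rolling_max(rolling_min(x, window_px), window_px),
                       max(2L, window_px %/% 2L))
  resid <- x - base
  out <- pmax(resid - stats::median(resid), 0)
  new_lane_profile(out, lane = profile$lane, baselined = TRUE)
}

# strict-ish local maxima with plateau handling: the center of each
# maximal run of equal values higher than both flanking values.
local_maxima <- function(x) {
  n <- length(x)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  out <- integer(0)
  for (j in seq_len(k)) {
    left_ok <- j == 1L || r$values[j - 1L] < r$values[j]
    right_ok <- j == k || r$values[j + 1L] < r$values[j]
    if (left_ok && right_ok && !(j == 1L && j == k))
      out <- c(out, as.integer(floor((starts[j] + ends[j]) / 2)))
  }
  out
}

# topographic prominence of peak at index i (1-based)
peak_prominence <- function(x, i) {
  h <- x[i]
  n <- length(x)
  higher_l <- which(x[seq_len(i - 1L)] > h)
  lo <- if (length(higher_l)) max(higher_l) else 1L
  valley_l <- min(x[lo:i])
  higher_r <- which(x[i:n] > h) + i - 1L
  hi <- if (length(higher_r)) min(higher_r) else n
  valley_r <- min(x[i:hi])
  h - max(valley_l, valley_r)
}

#' Detect peaks in a lane profile
#'
#' Finds local maxima whose topographic prominence is at least
#' `min_prominence_frac` times the profile's global maximum, enforcing a
#' minimum separation between retained apices (higher peaks win). Peaks are
#' returned well-to-bottom and numbered from 1, the convention used when
#' reading densitometric traces.
#'
#' @param profile A baselined `lane_profile` (raw profiles are accepted but
#'   the prominence threshold then includes the background level).
#' @param min_prominence_frac Fraction of the global maximum a peak's
#'   prominence must reach; in `(0, 1]`. Default 0.02.
#' @param min_separation_px Minimum apex separation in px; default 4 (twice
#'   the default rendered band sigma).
#' @return `data.frame` with columns `peak`, `apex_px` (0-based), `height`.
#'   A flat or empty profile yields zero rows.
#' @export
detect_peaks <- function(profile, min_prominence_frac = 0.02,
                         min_separation_px = 4L) {
  stopifnot(inherits(profile, "lane_profile"))
  if (min_prominence_frac <= 0 || min_prominence_frac > 1)
    stop("min_prominence_frac must be in (0, 1]")
  x <- profile$intensities
  empty <- data.frame(peak = integer(0), apex_px = integer(0),
                      height = numeric(0))
  gmax <- max(x)
  if (gmax <= 0 || length(unique(x)) == 1L) return(empty)
  idx <- local_maxima(x)
  if (length(idx) == 0L) return(empty)
  prom <- vapply(idx, function(i) peak_prominence(x, i), numeric(1))
  idx <- idx[prom >= min_prominence_frac * gmax]
  if (length(idx) == 0L) return(empty)
  # greedy separation filter, tallest first
  keep <- integer(0)
  for (i in idx[order(-x[idx])]) {
    if (all(abs(i - keep) >= min_separation_px)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  data.frame(peak = seq_along(keep), apex_px = keep - 1L, height = x[keep])
}

trapezoid <- function(x) {
  if (length(x) < 2L) return(0)
  sum((x[-1] + x[-length(x)]) / 2)
}

#' Integrate peak areas and normalize to area percentages
#'
#' Assigns integration boundaries by the valley rule — the minimum of the
#' profile between adjacent apices — and integrates each peak by the
#' trapezoidal rule on the pixel grid (half-open intervals, no sub-pixel
#' refinement). Each peak's extent is additionally capped where the profile
#' falls below `boundary_frac` of that peak's height, and at
#' `max_halfwidth_px` from the apex: on a noisy profile an unbounded
#' interval would integrate clipped noise far from any band, biasing the
#' area shares. Because the cap is relative to each peak's own height it
#' removes the same (negligible) tail fraction from every peak, leaving
#' area ratios unchanged. `area_percent` is each peak's share of the lane's
#' summed peak areas, normalized to 100. Alternatively,
#' `method = "gaussian"` fits a sum of Gaussians to the profile and uses the
#' analytic component areas — useful when bands merge and the valley rule
#' misallocates overlap.
#'
#' @param profile A baselined `lane_profile`.
#' @param peaks Output of [detect_peaks()] (>= 1 row).
#' @param method `"valley"` (default) or `"gaussian"`.
#' @param boundary_frac Outer extent threshold as a fraction of each peak's
#'   height (default 0.002).
#' @param max_halfwidth_px Hard cap on the half-width of one peak's
#'   integration interval (default 20).
#' @return `peaks` with added columns `left_px`, `right_px` (0-based,
#'   half-open), `area`, `area_percent`.
#' @export
integrate_peaks <- function(profile, peaks, method = c("valley", "gaussian"),
                            boundary_frac = 0.002, max_halfwidth_px = 20L) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "lane_profile"), is.data.frame(peaks),
            boundary_frac > 0, boundary_frac < 1, max_halfwidth_px >= 2)
  if (nrow(peaks) == 0L) stop("no peaks to integrate")
  x <- profile$intensities
  n <- length(x)
  apex1 <- peaks$apex_px + 1L  # 1-based
  if (is.unsorted(apex1, strictly = TRUE)) stop("peak apices must be increasing")

  k <- nrow(peaks)
  bounds <- integer(k + 1L)
  bounds[1] <- 1L
  bounds[k + 1L] <- n
  if (k > 1L) for (j in seq_len(k - 1L)) {
    seg <- apex1[j]:apex1[j + 1L]
    bounds[j + 1L] <- seg[which.min(x[seg])]
  }
  if (is.unsorted(bounds)) stop("internal error: overlapping peak bounds")

  # per-peak extents: valley bounds, tightened by the relative-height
  # threshold and the hard half-width cap
  lefts <- integer(k)
  rights <- integer(k)
  for (j in seq_len(k)) {
    thr <- boundary_frac * x[apex1[j]]
    l <- max(bounds[j], apex1[j] - max_halfwidth_px)
    below <- which(x[l:apex1[j]] < thr)
    if (length(below)) l <- l + max(below) - 1L + 1L
    r <- min(bounds[j + 1L], apex1[j] + max_halfwidth_px)
    below <- which(x[apex1[j]:r] < thr)
    if (length(below)) r <- apex1[j] + min(below) - 1L - 1L
    lefts[j] <- l
    rights[j] <- r
  }

  if (method == "valley") {
    area <- vapply(seq_len(k), function(j)
      trapezoid(x[lefts[j]:rights[j]]), numeric(1))
  } else {
    area <- gaussian_component_areas(x, apex1, peaks$height)
  }
  if (any(area <= 0)) stop("non-positive peak area; check baseline and bounds")
  peaks$left_px <- lefts - 1L
  peaks$right_px <- rights - 1L
  peaks$area <- area
  peaks$area_percent <- 100 * area / sum(area)
  peaks
}

# least-squares fit of a k-component Gaussian mixture to the profile;
# returns analytic areas amplitude * sigma * sqrt(2*pi)
gaussian_component_areas <- function(x, apex1, height) {
  k <- length(apex1)
  pos <- seq_along(x)
  par0 <- c(as.numeric(rbind(height, apex1, rep(2, k))))
  model <- function(p) {
    y <- numeric(length(x))
    for (j in seq_len(k)) {
      a <- p[3 * j - 2]; mu <- p[3 * j - 1]; s <- p[3 * j]
      y <- y + a * exp(-(pos - mu)^2 / (2 * s^2))
    }
    y
  }
  fit <- stats::nlminb(par0, function(p) sum((x - model(p))^2),
                       lower = rep(c(0, 1, 0.5), k),
                       upper = rep(c(Inf, length(x), length(x) / 2), k))
  p <- fit$par
  vapply(seq_len(k), function(j)
    p[3 * j - 2] * p[3 * j] * sqrt(2 * pi), numeric(1))
}

#' Fit a fragment-size calibration from a ladder lane
#'
#' Detects the ladder bands and fits the log-linear migration model
#' `position_px = a - b * log10(size_bp)` by least squares.
#'
#' @param ladder_profile A baselined `lane_profile` of the ladder lane.
#' @param ladder_sizes_bp Known ladder fragment sizes in bp, in descending
#'   order (top of the gel first); >= 3 values.
#' @param ... Passed to [detect_peaks()].
#' @return An object of class `size_calibration`: list with `a`, `b`,
#'   `residual_rms_px`, `n_bands`.
#' @export
calibrate_sizes <- function(ladder_profile, ladder_sizes_bp, ...) {
  sizes <- as.numeric(ladder_sizes_bp)
  if (length(sizes) < 3L)
    stop("size calibration needs >= 3 ladder bands, got ", length(sizes))
  if (is.unsorted(rev(sizes), strictly = TRUE))
    stop("ladder_sizes_bp must be strictly descending (top of gel first)")
  pk <- detect_peaks(ladder_profile, ...)
  if (nrow(pk) != length(sizes))
    stop("detected ", nrow(pk), " ladder bands but ", length(sizes),
         " sizes were given")
  fit <- stats::lm(pk$apex_px ~ log10(sizes))
  b <- -unname(stats::coef(fit)[2])
  if (b <= 0) stop("fitted migration slope b must be > 0; check the ladder")
  structure(
    list(a = unname(stats::coef(fit)[1]), b = b,
         residual_rms_px = sqrt(mean(stats::residuals(fit)^2)),
         n_bands = length(sizes)),
    class = "size_calibration")
}

#' @export
print.size_calibration <- function(x, ...) {
  cat(sprintf(
    "<size_calibration> position = %.2f - %.2f log10(bp); RMS %.3g px (%d bands)\n",
    x$a, x$b, x$residual_rms_px, x$n_bands))
  invisible(x)
}

#' Convert migration positions to fragment sizes (and back)
#'
#' @param calibration A [calibrate_sizes()] result, or a
#'   [gel_render_spec()] whose migration model serves as an exact
#'   calibration for synthetic scenes.
#' @param position_px Row position(s), 0-based.
#' @return Fragment size(s) in bp.
#' @export
size_at_position <- function(calibration, position_px) {
  ab <- calibration_ab(calibration)
  10^((ab[1] - position_px) / ab[2])
}

#' @rdname size_at_position
#' @param size_bp Fragment size(s) in bp.
#' @export
position_at_size <- function(calibration, size_bp) {
  ab <- calibration_ab(calibration)
  ab[1] - ab[2] * log10(size_bp)
}

calibration_ab <- function(calibration) {
  if (inherits(calibration, "size_calibration"))
    c(calibration$a, calibration$b)
  else if (inherits(calibration, "gel_render_spec"))
    unname(calibration$migration)
  else stop("calibration must be a size_calibration or gel_render_spec")
}

#' Attach calibrated fragment sizes to a peak table
#'
#' @param peaks Output of [integrate_peaks()] (or [detect_peaks()]).
#' @param calibration See [size_at_position()].
#' @return `peaks` with a `size_bp` column.
#' @export
assign_peak_sizes <- function(peaks, calibration) {
  peaks$size_bp <- size_at_position(calibration, peaks$apex_px)
  peaks
}

#' Label sized peaks with allele provenance
#'
#' Matches each expected allele of an informative call (recipient-exclusive,
#' donor-exclusive, shared) to the nearest detected peak within a size
#' tolerance. Each expected allele claims at most one peak; peaks claimed by
#' no allele are labelled `unassigned`. The default tolerance is half the
#' repeat spacing, so adjacent STR alleles can never be merged into one
#' assignment.
#'
#' @param peaks Peak table with a `size_bp` column (see
#'   [assign_peak_sizes()]).
#' @param call An [classify_alleles()] result.
#' @param locus The [str_locus()] mapping alleles to fragment sizes;
#'   defaults to the panel locus named in `call`.
#' @param tolerance_bp Matching tolerance in bp (default
#'   `repeat_unit_bp / 2`).
#' @return `peaks` with added columns `allele` (repeat count, `NA` if
#'   unassigned) and `label` (`recipient_exclusive`, `donor_exclusive`,
#'   `shared`, `unassigned`).
#' @export
match_peaks_to_alleles <- function(peaks, call,
                                   locus = panel_locus(default_panel(), call$locus),
                                   tolerance_bp = locus$repeat_unit_bp / 2) {
  stopifnot(is.data.frame(peaks), inherits(call, "informative_call"),
            inherits(locus, "str_locus"))
  if (is.null(peaks$size_bp))
    stop("peaks carry no size_bp; run assign_peak_sizes() first")
  expected <- data.frame(
    allele = c(call$recipient_exclusive, call$donor_exclusive, call$shared),
    label = rep(c("recipient_exclusive", "donor_exclusive", "shared"),
                c(length(call$recipient_exclusive),
                  length(call$donor_exclusive), length(call$shared))),
    stringsAsFactors = FALSE)
  expected$size_bp <- allele_size_bp(locus, expected$allele)

  peaks$allele <- NA_real_
  peaks$label <- "unassigned"
  if (nrow(peaks) == 0L) return(peaks)

  dist <- abs(outer(peaks$size_bp, expected$size_bp, "-"))
  for (i in seq_len(nrow(peaks))) {
    close <- which(dist[i, ] <= tolerance_bp)
    if (length(close) > 1L)
      stop("ambiguous peak at ", sprintf("%.1f", peaks$size_bp[i]),
           " bp: expected alleles ",
           paste(expected$allele[close], collapse = " and "),
           " both lie within ", tolerance_bp, " bp")
  }
  claimed_peaks <- integer(0)
  for (j in order(apply(dist, 2, min))) {  # most confident alleles first
    cand <- setdiff(which(dist[, j] <= tolerance_bp), claimed_peaks)
    if (length(cand) == 0L) next
    i <- cand[which.min(dist[cand, j])]
    peaks$allele[i] <- expected$allele[j]
    peaks$label[i] <- expected$label[j]
    claimed_peaks <- c(claimed_peaks, i)
  }
  peaks
}

#' Write a peak table as TSV
#'
#' @param peaks Labelled peak table.
#' @param path Output TSV path.
#' @param lane Lane index recorded in the output.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path, lane = NA_integer_) {
  out <- data.frame(lane = lane, peak = peaks$peak, apex_px = peaks$apex_px,
                    size_bp = if (is.null(peaks$size_bp)) NA_real_ else round(peaks$size_bp, 2),
                    height = round(peaks$height, 4),
                    area = round(peaks$area, 4),
                    area_percent = round(peaks$area_percent, 2),
                    label = if (is.null(peaks$label)) NA_character_ else peaks$label)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
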