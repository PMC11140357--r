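#' Rendering specification for a synthetic silver-stained gel
#'
#' Parameterizes the synthetic PAGE renderer. Migration follows the standard
#' log-linear electrophoretic mobility approximation
#' `row_px = a - b * log10(size_bp)` (larger fragments migrate less, i.e.
#' stay nearer the wells at row 0). Bands are 2D Gaussians in the
#' migration x lane-width plane; the background is a smooth vertical
#' gradient; noise is additive Gaussian on pixel intensities, clipped to the
#' bit depth — the model of a photographed stained gel, not of photon
#' counting.
#'
#' @param n_lanes Number of lanes (>= 1).
#' @param image_height_px,lane_width_px Image geometry in pixels.
#' @param lane_gap_px Gap between adjacent lanes (and at the image edges).
#' @param migration Numeric `c(a, b)` of the migration model; `b > 0`.
#' @param band_sigma_px Gaussian band spread along migration, in px.
#' @param background Numeric `c(offset, slope)`: background intensity at the
#'   well and its per-row vertical gradient, in intensity units.
#' @param noise_sd Additive Gaussian noise SD in intensity units (>= 0).
#' @param amount_gain Integrated intensity contributed per unit band amount.
#' @param bit_depth 8 or 16.
#' @param polarity `"dark"` (silver stain: bands darker than background) or
#'   `"light"` (inverted).
#' @param seed Integer RNG seed for the noise field.
#' @return An object of class `gel_render_spec`.
#' @export
gel_render_spec <- function(n_lanes = 1L,
                            image_height_px = 512L,
                            lane_width_px = 24L,
                            lane_gap_px = 6L,
                            migration = c(a = 2183, b = 850),
                            band_sigma_px = 1.5,
                            background = c(offset = 200, slope = 0.02),
                            noise_sd = 1,
                            amount_gain = 60,
                            bit_depth = 8L,
                            polarity = c("dark", "light"),
                            seed = 1L) {
  polarity <- match.arg(polarity)
  stopifnot(n_lanes >= 1, image_height_px >= 16, lane_width_px >= 4,
            lane_gap_px >= 0, length(migration) == 2, band_sigma_px > 0,
            length(background) == 2, noise_sd >= 0, amount_gain > 0,
            bit_depth %in% c(8L, 16L))
  if (migration[2] <= 0)
    stop("migration coefficient b must be > 0 (larger fragments migrate less)")
  structure(
    list(n_lanes = as.integer(n_lanes),
         image_height_px = as.integer(image_height_px),
         lane_width_px = as.integer(lane_width_px),
         lane_gap_px = as.integer(lane_gap_px),
         migration = stats::setNames(as.numeric(migration), c("a", "b")),
         band_sigma_px = band_sigma_px,
         background = stats::setNames(as.numeric(background), c("offset", "slope")),
         noise_sd = noise_sd, amount_gain = amount_gain,
         bit_depth = as.integer(bit_depth), polarity = polarity,
         seed = as.integer(seed)),
    class = "gel_render_spec"
  )
}

#' Migration position of a fragment
#'
#' @param spec A [gel_render_spec()].
#' @param size_bp Fragment size(s) in bp.
#' @return Continuous row position(s) in px, 0-based from the well.
#' @export
migration_position <- function(spec, size_bp) {
  spec$migration["a"] - spec$migration["b"] * log10(size_bp)
}

#' Fragment size at a migration position (renderer's own model)
#'
#' @param spec A [gel_render_spec()].
#' @param row_px Row position(s), 0-based.
#' @return Fragment size(s) in bp.
#' @export
migration_size <- function(spec, row_px) {
  10^((spec$migration["a"] - row_px) / spec$migration["b"])
}

lane_bounds <- function(spec) {
  x_start <- spec$lane_gap_px +
    (seq_len(spec$n_lanes) - 1L) * (spec$lane_width_px + spec$lane_gap_px)
  data.frame(lane = seq_len(spec$n_lanes),
             x_start = x_start, x_end = x_start + spec$lane_width_px)
}

# Evaluate expr with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render a synthetic gel image
#'
#' Renders each band as a 2D Gaussian (sigma `band_sigma_px` along
#' migration, `lane_width_px / 6` across the lane) whose total integrated
#' intensity is exactly `amount * amount_gain`, superimposed (as darkening,
#' for silver-stain polarity) on a smooth vertical background gradient, with
#' optional additive Gaussian noise. Deterministic for a fixed spec seed.
#'
#' @param spec A [gel_render_spec()].
#' @param bands `data.frame` with columns `lane` (1-based), `size_bp`,
#'   `amount` (>= 0), and optionally `label` (carried into the ground
#'   truth).
#' @return A list with elements:
#'   * `image`: object of class `gel_image` — fields `pixels` (matrix,
#'     rows = migration from the well), `bit_depth`, `polarity`, `lanes`
#'     (0-based half-open column intervals), `spec`;
#'   * `truth`: `data.frame` of ground truth per band (`lane`, `size_bp`,
#'     `amount`, `center_px`, `area` = integrated rendered signal, plus any
#'     `label`).
#' @examples
#' spec <- gel_render_spec(n_lanes = 1, noise_sd = 0)
#' gel <- render_gel(spec, data.frame(lane = 1, size_bp = c(140, 180),
#'                                    amount = c(2, 1)))
#' gel$truth
#' @export
render_gel <- function(spec, bands) {
  stopifnot(inherits(spec, "gel_render_spec"), is.data.frame(bands),
            all(c("lane", "size_bp", "amount") %in% names(bands)))
  if (any(bands$amount < 0)) stop("band amounts must be >= 0")
  if (any(bands$lane < 1 | bands$lane > spec$n_lanes))
    stop("band lane index outside 1..", spec$n_lanes)
  h <- spec$image_height_px
  lanes <- lane_bounds(spec)
  w <- max(lanes$x_end) + spec$lane_gap_px
  centers <- migration_position(spec, bands$size_bp)
  margin <- 3 * spec$band_sigma_px
  bad <- centers < margin | centers > h - 1 - margin
  if (any(bad))
    stop("band size(s) ", paste(bands$size_bp[bad], collapse = ", "),
         " bp fall outside the rendered size window (",
         sprintf("%.0f-%.0f bp", migration_size(spec, h - 1 - margin),
                 migration_size(spec, margin)), ")")

  sig <- matrix(0, nrow = h, ncol = w)
  sigma_col <- spec$lane_width_px / 6
  rows0 <- 0:(h - 1)
  cols0 <- 0:(w - 1)
  for (i in seq_len(nrow(bands))) {
    lb <- lanes[bands$lane[i], ]
    cc <- (lb$x_start + lb$x_end - 1) / 2
    krow <- exp(-(rows0 - centers[i])^2 / (2 * spec$band_sigma_px^2))
    kcol <- exp(-(cols0 - cc)^2 / (2 * sigma_col^2))
    kern <- outer(krow, kcol)
    # normalize the discrete kernel so the band's integral is exact
    sig <- sig + (bands$amount[i] * spec$amount_gain) * kern / sum(kern)
  }

  maxval <- 2^spec$bit_depth - 1
  bg <- spec$background["offset"] + spec$background["slope"] * rows0
  bgm <- matrix(bg, nrow = h, ncol = w)
  base <- if (spec$polarity == "dark") bgm - sig else (maxval - bgm) + sig
  if (spec$noise_sd > 0)
    base <- base + with_seed(spec$seed,
                             matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w))
  pixels <- pmin(pmax(base, 0), maxval)

  truth <- bands
  truth$center_px <- as.numeric(centers)
  truth$area <- truth$amount * spec$amount_gain
  image <- structure(
    list(pixels = pixels, bit_depth = spec$bit_depth,
         polarity = spec$polarity, lanes = lanes, spec = spec),
    class = "gel_image")
  list(image = image, truth = truth)
}

#' @export
print.gel_image <- function(x, ...) {
  cat(sprintf("<gel_image> %d x %d px, %d-bit, %s bands, %d lane(s)\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$polarity,
              nrow(x$lanes)))
  invisible(x)
}

#' Write a gel image to a grayscale PNG or TIFF file
#'
#' PNG output is 8-bit (the writer's limit); TIFF output stores 16-bit
#' samples regardless of the image's nominal bit depth, so that
#' re-quantification from the file is not limited by quantization.
#'
#' @param image A `gel_image`.
#' @param path Output path; format chosen by extension (`.png` or `.tif`).
#' @return `path`, invisibly.
#' @export
write_gel_image <- function(image, path) {
  stopifnot(inherits(image, "gel_image"))
  maxval <- 2^image$bit_depth - 1
  norm <- image$pixels / maxval
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(norm, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is needed to write TIFF files")
    tiff::writeTIFF(norm, path, bits.per.sample = 16L)
  } else stop("unsupported image extension: ", path)
  invisible(path)
}

#' Read a grayscale gel image
#'
#' Reads an 8/16-bit grayscale PNG or TIFF and attaches the lane geometry
#' and polarity needed for densitometry.
#'
#' @param path Image path.
#' @param lanes `data.frame` with columns `x_start`, `x_end` (0-based,
#'   half-open pixel columns per lane).
#' @param polarity `"dark"` or `"light"` band polarity.
#' @param bit_depth Nominal bit depth of the stored image.
#' @return A `gel_image`.
#' @export
read_gel_image <- function(path, lanes, polarity = c("dark", "light"),
                           bit_depth = 8L) {
  polarity <- match.arg(polarity)
  raw <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is needed to read TIFF files")
    tiff::readTIFF(path)
  } else stop("unsupported image extension: ", path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]  # collapse RGB/gray-alpha
  stopifnot(is.data.frame(lanes), all(c("x_start", "x_end") %in% names(lanes)))
  if (is.null(lanes$lane)) lanes$lane <- seq_len(nrow(lanes))
  if (any(lanes$x_start < 0) || any(lanes$x_end > ncol(raw)))
    stop("lane intervals fall outside the image width")
  maxval <- 2^as.integer(bit_depth) - 1
  structure(
    list(pixels = raw * maxval, bit_depth = as.integer(bit_depth),
         polarity = polarity, lanes = lanes, spec = NULL),
    class = "gel_image")
}

#' Render a post-transplant chimera lane with known donor fraction
#'
#' Builds one lane's band set from an informative-allele call so that the
#' designed donor-chimerism percentage — under the simple-complement
#' definition, i.e. 100 minus the recipient-exclusive share of total band
#' area — equals `donor_fraction * 100`. The recipient-exclusive bands carry
#' `(1 - donor_fraction)` of the total amount (split by recipient allele
#' dosage); all remaining bands (shared and donor-exclusive) carry
#' `donor_fraction` of it, split by combined allele dosage, so a homozygous
#' donor renders as one thick band of double weight. Raw area is used — no
#' dosage correction — matching how gel densitometry reads such lanes.
#'
#' @param call An [classify_alleles()] result with at least one
#'   recipient-exclusive allele.
#' @param donor_fraction Designed donor fraction in `[0, 1]`.
#' @param spec A [gel_render_spec()].
#' @param locus The [str_locus()] giving the allele -> fragment-size map;
#'   defaults to the panel locus named in `call`.
#' @param lane Lane index to render into (default 1).
#' @param total_amount Total band amount in the lane (default 100, so
#'   amounts read as percentages).
#' @return As [render_gel()]: list of `image` and `truth`; the truth table
#'   carries `allele`, `label` (`recipient_exclusive`, `donor_exclusive`,
#'   `shared`) and `designed_percent` per band.
#' @examples
#' call <- classify_alleles(genotype("D5S818", c(12, 12)),
#'                          genotype("D5S818", c(10, 12)))
#' spec <- gel_render_spec(noise_sd = 0)
#' scene <- make_chimera_lane(call, donor_fraction = 0.606, spec)
#' scene$truth[, c("allele", "label", "designed_percent")]
#' @export
make_chimera_lane <- function(call, donor_fraction, spec,
                              locus = panel_locus(default_panel(), call$locus),
                              lane = 1L, total_amount = 100) {
  stopifnot(inherits(call, "informative_call"),
            inherits(spec, "gel_render_spec"), inherits(locus, "str_locus"))
  if (length(call$recipient_exclusive) == 0L)
    stop("locus ", call$locus,
         " has no recipient-exclusive allele; cannot design a chimera lane")
  if (donor_fraction < 0 || donor_fraction > 1)
    stop("donor_fraction must be in [0, 1]")
  if (locus$name != call$locus)
    stop("locus object (", locus$name, ") does not match call locus (",
         call$locus, ")")

  d_dose <- allele_dosage(call$donor)
  r_dose <- allele_dosage(call$recipient)
  alleles <- sort(unique(c(call$donor$alleles, call$recipient$alleles)))
  label <- ifelse(alleles %in% call$recipient_exclusive, "recipient_exclusive",
                  ifelse(alleles %in% call$donor_exclusive, "donor_exclusive",
                         "shared"))
  key <- as.character(alleles)
  weight <- ifelse(label == "recipient_exclusive",
                   r_dose[key],
                   ifelse(label == "shared",
                          d_dose[key] + r_dose[key], d_dose[key]))
  amount <- numeric(length(alleles))
  rex <- label == "recipient_exclusive"
  amount[rex] <- (1 - donor_fraction) * total_amount * weight[rex] / sum(weight[rex])
  if (any(!rex))
    amount[!rex] <- donor_fraction * total_amount * weight[!rex] / sum(weight[!rex])

  bands <- data.frame(lane = lane, size_bp = allele_size_bp(locus, alleles),
                      amount = amount, allele = alleles, label = label,
                      stringsAsFactors = FALSE)
  out <- render_gel(spec, bands)
  out$truth$designed_percent <- 100 * out$truth$amount / sum(out$truth$amount)
  out
}
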