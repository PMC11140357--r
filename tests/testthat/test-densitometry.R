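test_that("lane profiles are polarity-normalized means over lane columns", {
  spec <- gel_render_spec(noise_sd = 0)
  # uniform image: constant profile
  flat <- render_gel(spec, data.frame(lane = 1, size_bp = 200, amount = 0))
  spec_flat <- gel_render_spec(noise_sd = 0, background = c(120, 0))
  flat <- render_gel(spec_flat, data.frame(lane = 1, size_bp = 200, amount = 0))
  prof <- extract_lane_profile(flat$image, 1)
  expect_equal(diff(range(prof$intensities)), 0)

  # noise-free single band: profile maximum at the ground-truth center
  gel <- render_gel(spec, data.frame(lane = 1, size_bp = 180, amount = 30))
  prof <- extract_lane_profile(gel$image, 1)
  based <- subtract_baseline(prof)
  expect_lte(abs((which.max(based$intensities) - 1) - gel$truth$center_px), 1)

  # dark-band scene and its pre-inverted counterpart give identical profiles
  inv <- gel$image
  inv$pixels <- (2^inv$bit_depth - 1) - inv$pixels
  inv$polarity <- "light"
  expect_equal(extract_lane_profile(inv, 1)$intensities, prof$intensities)

  expect_error(extract_lane_profile(gel$image, 3), "out of range")
})

test_that("baseline subtraction removes offsets and gradients, keeps peaks", {
  # constant offset: all zeros
  prof <- lane_profile(rep(7.5, 64))
  out <- subtract_baseline(prof, 5)
  expect_equal(out$intensities, rep(0, 64))

  # linear ramp + narrow Gaussian: peak area preserved within 2%
  n <- 400
  h <- 50; s <- 2
  x <- 3 + 0.05 * (seq_len(n) - 1) + gaussian_profile(n, 200, s, h)
  out <- subtract_baseline(lane_profile(x), 10)
  pk <- integrate_peaks(out, detect_peaks(out))
  expect_equal(pk$area, h * s * sqrt(2 * pi), tolerance = 0.02)

  # idempotence: an already-baselined profile passes through within clipping
  clean <- lane_profile(gaussian_profile(n, 200, s, h))
  once <- subtract_baseline(clean, 10)
  expect_equal(once$intensities, clean$intensities, tolerance = 1e-3)

  expect_error(subtract_baseline(prof, 2), "window_px")
  expect_error(subtract_baseline(prof, 64), "window_px")
})

test_that("peak detection matches a brute-force local-maxima oracle", {
  n <- 300
  x <- gaussian_profile(n, 90, 3, 40) + gaussian_profile(n, 200, 3, 20)
  prof <- lane_profile(x, baselined = TRUE)
  pk <- detect_peaks(prof)
  expect_equal(nrow(pk), 2L)
  expect_lte(abs(pk$apex_px[1] - 90), 1)
  expect_lte(abs(pk$apex_px[2] - 200), 1)
  expect_equal(pk$peak, 1:2)  # numbered from the well

  # oracle: exhaustive scan for strict local maxima
  oracle <- which(diff(sign(diff(x))) == -2) + 1L
  expect_setequal(pk$apex_px, oracle - 1L)

  # flat profile: no peaks, not an error
  expect_equal(nrow(detect_peaks(lane_profile(rep(0, 32)))), 0L)
  expect_equal(nrow(detect_peaks(lane_profile(rep(3, 32)))), 0L)
  expect_error(detect_peaks(prof, min_prominence_frac = 0), "prominence")

  # three-band scene: three peaks
  sc3 <- make_chimera_lane(fig3_call(), 0.794, gel_render_spec(noise_sd = 0))
  p3 <- subtract_baseline(extract_lane_profile(sc3$image, 1))
  expect_equal(nrow(detect_peaks(p3)), 3L)
})

test_that("valley-rule integration recovers analytic Gaussian area shares", {
  n <- 400
  # areas 2:1 via heights at equal sigma
  x <- gaussian_profile(n, 120, 3, 60) + gaussian_profile(n, 260, 3, 30)
  prof <- lane_profile(x, baselined = TRUE)
  pk <- integrate_peaks(prof, detect_peaks(prof))
  expect_equal(pk$area_percent, c(200 / 3, 100 / 3), tolerance = 0.5 / 66)
  expect_equal(sum(pk$area_percent), 100, tolerance = 1e-9)

  # single peak: 100%
  one <- lane_profile(gaussian_profile(n, 150, 3, 10), baselined = TRUE)
  pk1 <- integrate_peaks(one, detect_peaks(one))
  expect_equal(pk1$area_percent, 100)

  # gaussian deconvolution agrees on well-separated peaks
  pkg <- integrate_peaks(prof, detect_peaks(prof), method = "gaussian")
  expect_equal(pkg$area_percent, pk$area_percent, tolerance = 0.01)
})

test_that("size calibration recovers the generative migration model", {
  sizes <- c(350, 300, 250, 200, 150, 120)
  spec <- gel_render_spec(migration = c(a = 2183, b = 850), noise_sd = 0)
  gel <- render_gel(spec, data.frame(lane = 1, size_bp = sizes, amount = 10))
  lp <- subtract_baseline(extract_lane_profile(gel$image, 1))
  cal <- calibrate_sizes(lp, sizes)
  expect_equal(cal$a, 2183, tolerance = 1e-3)
  expect_equal(cal$b, 850, tolerance = 1e-3)

  # interpolation consistency: ladder band rows map back to their sizes
  pk <- detect_peaks(lp)
  expect_lt(max(abs(size_at_position(cal, pk$apex_px) - sizes)), 1)

  expect_error(calibrate_sizes(lp, c(300, 200)), ">= 3")
  expect_error(calibrate_sizes(lp, c(350, 300, 250)), "sizes were given")
})

test_that("peaks are labelled by nearest expected allele within tolerance", {
  spec <- gel_render_spec(noise_sd = 0)
  sc3 <- make_chimera_lane(fig3_call(), 0.794, spec)
  prof <- subtract_baseline(extract_lane_profile(sc3$image, 1))
  pk <- integrate_peaks(prof, detect_peaks(prof))
  pk <- assign_peak_sizes(pk, spec)
  pk <- match_peaks_to_alleles(pk, fig3_call())
  # middle peak (second from the well) is the recipient's exclusive allele
  expect_equal(pk$label[order(pk$apex_px)][2], "recipient_exclusive")

  sc1 <- make_chimera_lane(fig1_call(), 0.606, spec)
  prof1 <- subtract_baseline(extract_lane_profile(sc1$image, 1))
  pk1 <- integrate_peaks(prof1, detect_peaks(prof1))
  pk1 <- assign_peak_sizes(pk1, spec)
  pk1 <- match_peaks_to_alleles(pk1, fig1_call())
  expect_setequal(pk1$label, c("shared", "recipient_exclusive"))

  # a peak far from any expected allele stays unassigned
  far <- pk1
  far$size_bp <- far$size_bp + 30
  far <- match_peaks_to_alleles(far, fig1_call())
  expect_equal(unique(far$label), "unassigned")

  # two expected alleles within tolerance of one peak is ambiguous
  expect_error(match_peaks_to_alleles(pk1, fig1_call(), tolerance_bp = 10),
               "ambiguous")
  expect_error(match_peaks_to_alleles(pk1[, setdiff(names(pk1), "size_bp")],
                                      fig1_call()),
               "size_bp")
})

test_that("area shares are invariant to intensity scale and baseline offset", {
  n <- 400
  x <- gaussian_profile(n, 120, 3, 60) + gaussian_profile(n, 260, 3, 30)
  base_pct <- integrate_peaks(lane_profile(x), detect_peaks(lane_profile(x)))$area_percent
  for (k in c(0.2, 3, 117)) {
    px <- lane_profile(k * x)
    pct <- integrate_peaks(px, detect_peaks(px))$area_percent
    expect_equal(pct, base_pct, tolerance = 1e-9)
  }
  # constant offset removed by the baseline stage: < 0.2 points shift
  for (off in c(5, 40)) {
    po <- subtract_baseline(lane_profile(x + off), 10)
    pct <- integrate_peaks(po, detect_peaks(po))$area_percent
    expect_lt(max(abs(pct - base_pct)), 0.2)
  }
})
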