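test_that("windowed-median background matches the brute-force oracle", {
  set.seed(10)
  img <- matrix(rnorm(45 * 38, 100, 8), 45, 38)
  for (w in c(5L, 9L)) {
    est <- estimate_local_background(img, w)
    oracle <- brute_force_median_filter(img, w)
    # implementation quantizes the image range onto 65536 levels
    expect_lt(max(abs(est - oracle)), diff(range(img)) / 65535)
  }
})

test_that("background estimate is robust to spots and follows ramps", {
  expect_equal(estimate_local_background(matrix(7.3, 30, 30), 5L),
               matrix(7.3, 30, 30))
  # constant + one PSF spot: background under the spot stays within 1%
  oc <- optics_config(image_shape = c(64L, 64L), illumination = "flat",
                      shot_noise = FALSE, read_noise_sigma = 0,
                      background_level = 50, seed = 1)
  img <- render_fov(data.frame(x = 31, y = 31, yoyo_intensity = 20000,
                               cy5_intensity = 0), oc)$yoyo
  bg <- estimate_local_background(img, 31L)
  expect_equal(bg[32, 32], 50, tolerance = 0.01)
  # linear ramp, no spots: interior background equals the ramp within half
  # a gray level
  ramp <- outer(seq(0, 60, length.out = 80), rep(1, 70))
  bgr <- estimate_local_background(ramp, 11L)
  interior <- 6:75
  expect_lt(max(abs(bgr[interior, ] - ramp[interior, ])), 0.5)
  expect_error(estimate_local_background(ramp, 81L), "smaller")
  expect_error(estimate_local_background(ramp, 10L), "odd")
})

test_that("a single clean spot is measured to 2% and located to 0.1 px", {
  oc <- optics_config(image_shape = c(128L, 128L), illumination = "flat",
                      shot_noise = FALSE, read_noise_sigma = 0, seed = 1)
  truth <- data.frame(x = 63.3, y = 60.7, yoyo_intensity = 10000,
                      cy5_intensity = 0)
  img <- render_fov(truth, oc)$yoyo
  expect_equal(nrow(detect_spots(matrix(5, 64, 64))), 0) # flat image
  sp <- detect_spots(img)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$integrated_intensity, 10000, tolerance = 0.02)
  expect_lt(abs(sp$x - 63.3), 0.1)
  expect_lt(abs(sp$y - 60.7), 0.1)
  expect_false(sp$flagged)
})

test_that("nearby but separated spots are resolved as two detections", {
  oc <- optics_config(image_shape = c(96L, 96L), illumination = "flat",
                      shot_noise = FALSE, read_noise_sigma = 0, seed = 1)
  p <- detection_params()
  gap <- 3 * p$min_separation
  img <- render_fov(data.frame(x = c(40, 40 + gap), y = c(48, 48),
                               yoyo_intensity = c(8000, 8000),
                               cy5_intensity = c(0, 0)), oc)$yoyo
  expect_equal(nrow(detect_spots(img, p)), 2)
})

test_that("detection is invariant to a constant intensity offset", {
  # property of the local background subtraction; flat-fielding is off
  # because an un-subtracted camera bias is indistinguishable from
  # illumination shape in the background map (see the methods vignette)
  oc <- small_optics(illumination = "flat")
  cfg <- ladder_config(count = 6L, seed = 31)
  ds <- simulate_dataset(cfg, oc, out_dir = NULL, molecules_per_fov = 60L)
  img <- ds$images[[1]]$yoyo
  p <- detection_params(flatfield = FALSE)
  s1 <- detect_spots(img, p)
  s2 <- detect_spots(img + 500, p)
  expect_equal(nrow(s1), nrow(s2))
  expect_equal(s1$integrated_intensity, s2$integrated_intensity,
               tolerance = 1e-6)
})

test_that("clean simulations are recovered with recall/precision >= 0.99 and
           unit intensity slope", {
  cfg <- ladder_config(count = 120L, seed = 17)
  rd <- render_and_detect(cfg, optics_config(seed = 55),
                          molecules_per_fov = 300L)
  yo <- rd$spots[rd$spots$channel == "yoyo" & !rd$spots$flagged, ]
  n_truth <- nrow(rd$ground_truth)
  m <- match_to_truth(yo, rd$ground_truth)
  hits <- m[, "dist"] < 2
  expect_gte(sum(hits) / n_truth, 0.99)              # recall
  expect_gte(mean(hits), 0.99)                       # precision
  # illumination-corrected intensities regress on truth with slope 1 +- 0.03
  fit <- lm(yo$integrated_intensity[hits] ~ m[hits, "yoyo_intensity"])
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.03)
  # intercept consistent with zero photometry noise floor (au scale ~2e4)
  expect_lt(abs(unname(coef(fit)[1])), 50)
})

test_that("saturated and edge spots are flagged", {
  oc <- optics_config(image_shape = c(64L, 64L), illumination = "flat",
                      shot_noise = FALSE, read_noise_sigma = 0, seed = 1)
  img <- render_fov(data.frame(x = c(30, 2), y = c(30, 30),
                               yoyo_intensity = c(5e6, 8000),
                               cy5_intensity = c(0, 0)), oc)$yoyo
  sp <- detect_spots(img, detection_params(saturation_value = 60000))
  expect_true(any(sp$saturated))
  expect_true(any(sp$edge))
  expect_true(all(sp$flagged))
})

test_that("extract_intensities walks a directory and skips odd FOVs", {
  dir <- withr::local_tempdir()
  expect_equal(nrow(extract_intensities(dir, verbose = FALSE)), 0)
  cfg <- ladder_config(count = 10L, seed = 3)
  simulate_dataset(cfg, small_optics(), dir, molecules_per_fov = 50L)
  spots <- extract_intensities(dir, verbose = FALSE)
  expect_equal(sum(spots$channel == "yoyo"), 100)
  # remove one channel file: FOV skipped with a warning
  file.remove(file.path(dir, "fov002_cy5.tif"))
  expect_warning(s2 <- extract_intensities(dir, verbose = FALSE), "skipped")
  expect_false(2L %in% s2$fov)
})
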