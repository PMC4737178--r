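test_that("noise-free intensities are exactly gain * length * quench", {
  cfg <- sim_config(data.frame(length_bp = c(3000, 1200), count = c(1, 2)),
                    reference_populations = data.frame(
                      length_bp = 5000, count = 2, quench_factor = 0.9),
                    intensity_gain = 1, intensity_cv = 0, seed = 4)
  mol <- simulate_molecules(cfg)
  expect_equal(nrow(mol), 5)
  expect_equal(mol$yoyo_intensity[mol$length_bp == 3000], 3000)
  expect_equal(sort(mol$yoyo_intensity[!mol$is_reference]),
               c(1200, 1200, 3000))
  expect_equal(mol$yoyo_intensity[mol$is_reference], rep(5000 * 0.9, 2))
  expect_true(all(mol$cy5_intensity[mol$is_reference] > 0))
  expect_true(all(mol$cy5_intensity[!mol$is_reference] == 0))
})

test_that("empty population list yields an empty molecule table", {
  cfg <- sim_config(data.frame(length_bp = integer(), count = integer()))
  expect_equal(nrow(simulate_molecules(cfg)), 0)
})

test_that("lognormal noise gives the closed-form mean exp(sigma^2/2)", {
  # E[g L e^eps] = g L exp(cv^2 / 2) = 1000 * exp(0.005) ~ 1005.0 au
  cfg <- sim_config(data.frame(length_bp = 1000, count = 10000),
                    intensity_gain = 1, intensity_cv = 0.10, seed = 99)
  mol <- simulate_molecules(cfg)
  expect_equal(mean(mol$yoyo_intensity), 1000 * exp(0.10^2 / 2),
               tolerance = 0.01)
})

test_that("configuration errors are rejected", {
  expect_error(sim_config(data.frame(length_bp = 100, count = -1)),
               "non-negative")
  expect_error(sim_config(data.frame(length_bp = 0, count = 1)), ">= 1 bp")
  expect_error(sim_config(data.frame(length_bp = 100, count = 1),
                          intensity_gain = 0), "positive")
  expect_error(sim_config(data.frame(length_bp = 100, count = 1),
                          reference_populations = data.frame(
                            length_bp = 100, count = 1, quench_factor = 1.2)),
               "quench_factor")
})

test_that("rendering conserves molecule flux and applies illumination", {
  oc <- optics_config(image_shape = c(96L, 96L), illumination = "flat",
                      shot_noise = FALSE, read_noise_sigma = 0,
                      background_level = 13.5, seed = 1)
  # zero molecules, no noise: image equals background * illumination
  img0 <- render_fov(data.frame(x = numeric(), y = numeric(),
                                yoyo_intensity = numeric(),
                                cy5_intensity = numeric()), oc)
  expect_equal(img0$yoyo, matrix(13.5, 96, 96))
  # one molecule: integrated background-free counts match its intensity
  mols <- data.frame(x = 47.2, y = 50.8, yoyo_intensity = 10000,
                     cy5_intensity = 0)
  img <- render_fov(mols, oc)$yoyo
  expect_equal(sum(img - 13.5), 10000, tolerance = 0.005)
  # two identical molecules under illumination 1.0 vs 0.5: counts ratio 2
  illum <- matrix(1, 96, 96); illum[, 49:96] <- 0.5
  oc2 <- optics_config(image_shape = c(96L, 96L), illumination = illum,
                       shot_noise = FALSE, read_noise_sigma = 0,
                       background_level = 0, seed = 1)
  img2 <- render_fov(data.frame(x = c(20, 70), y = c(20, 70),
                                yoyo_intensity = c(5000, 5000),
                                cy5_intensity = c(0, 0)), oc2)$yoyo
  s1 <- sum(img2[1:48, 1:48]); s2 <- sum(img2[49:96, 49:96])
  expect_equal(s1 / s2, 2, tolerance = 0.01)
})

test_that("out-of-bounds molecules are rejected with a warning", {
  oc <- optics_config(image_shape = c(64L, 64L), shot_noise = FALSE,
                      read_noise_sigma = 0, seed = 1)
  expect_warning(
    img <- render_fov(data.frame(x = c(30, 200), y = c(30, 10),
                                 yoyo_intensity = c(100, 100),
                                 cy5_intensity = c(0, 0)), oc),
    "outside image bounds")
})

test_that("ground-truth CSV round-trips exactly", {
  cfg <- ladder_config(count = 3L, seed = 8)
  mol <- simulate_molecules(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(mol, path)
  back <- read_ground_truth(path)
  expect_identical(back, mol)
  # empty table: header-only CSV
  empty <- mol[0, ]
  write_ground_truth(empty, path)
  expect_equal(nrow(read_ground_truth(path)), 0)
  expect_equal(names(read_ground_truth(path)), names(mol))
})

test_that("seeded dataset simulation is reproducible and respects layout", {
  cfg <- ladder_config(count = 12L, seed = 21)
  oc <- small_optics(min_spot_separation = 10)
  d1 <- simulate_dataset(cfg, oc, out_dir = NULL, molecules_per_fov = 60L)
  d2 <- simulate_dataset(cfg, oc, out_dir = NULL, molecules_per_fov = 60L)
  expect_identical(d1$ground_truth, d2$ground_truth)
  expect_identical(d1$images, d2$images)
  # min separation honored within each FOV
  for (f in unique(d1$ground_truth$fov)) {
    g <- d1$ground_truth[d1$ground_truth$fov == f, ]
    d <- as.matrix(dist(g[, c("x", "y")]))
    expect_gte(min(d[upper.tri(d)]), 10)
  }
})

test_that("TIFF round trip preserves the image to one gray level", {
  img <- matrix(runif(64 * 48, 0, 4000), 64, 48)
  path <- withr::local_tempfile(fileext = ".tif")
  write_fov_tiff(img, path)
  back <- read_fov_tiff(path)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1)
})
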