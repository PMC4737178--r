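test_that("mass arithmetic matches unit-tracking oracles", {
  # 1e6 molecules of 1000 bp: 1e6 * 1000 * 650 / 6.02214076e23 g = 1079.4 fg
  expect_equal(counts_to_mass(1000, 1e6), 1079.35, tolerance = 1e-4)
  # one 3000 bp molecule: 3.238e-3 fg
  expect_equal(counts_to_mass(3000, 1), 3.238e-3, tolerance = 1e-3)
  expect_equal(counts_to_mass(c(500, 1000), c(0, 0)), c(0, 0))
  expect_error(counts_to_mass(1000, -1), "non-negative")
  # custom base-pair mass propagates linearly
  expect_equal(counts_to_mass(1000, 10, m_bp = 325),
               counts_to_mass(1000, 10) / 2)
})

test_that("size distribution conserves counts and exact mass", {
  set.seed(3)
  lens <- c(rnorm(3000, 1000, 60), rnorm(2000, 5000, 300))
  dist <- size_distribution(lens, binning = 128L)
  expect_equal(sum(dist$count), length(lens))
  expect_equal(sampled_mass(dist), sum(bp_to_fg(lens)), tolerance = 1e-12)
  # bin-center mode approximates the exact mode closely at fine binning
  dist2 <- size_distribution(lens, binning = 128L, mode = "bin-center")
  expect_equal(sampled_mass(dist2), sampled_mass(dist), tolerance = 0.01)
  expect_equal(sampled_mass(dist[0, ]), 0)
})

test_that("population summary normalizes amounts to one", {
  set.seed(11)
  lens <- c(rnorm(4000, 1000, 60), rnorm(4000, 3000, 180))
  dist <- size_distribution(lens, binning = 200L)
  h <- structure(list(bin_edges = attr(dist, "bin_edges"),
                      mids = dist$bin_bp, counts = dist$mass_fg,
                      n_molecules = length(lens), weighted = TRUE),
                 class = "intensity_histogram")
  fit <- fit_gaussian_sum(h, initial_peaks(h, expected_k = 2))
  pops <- population_summary(fit)
  expect_equal(sum(pops$normalized_amount), 1, tolerance = 1e-12)
  # equal molecule counts: mass ratio = length ratio 3:1
  expect_equal(pops$normalized_amount[2] / pops$normalized_amount[1], 3,
               tolerance = 0.05)
  expect_equal(pops$length_bp, c(1000, 3000), tolerance = 0.01)
})

test_that("simulated ladder amounts are recovered within 5%", {
  cfg <- ladder_config(count = 2000L, seed = 14)
  mol <- simulate_molecules(cfg)
  # ideal sizing: intensities divided by the known gain and lognormal mean
  lens <- mol$yoyo_intensity / (2 * exp(0.06^2 / 2))
  dist <- size_distribution(lens, binning = 256L)
  h <- structure(list(bin_edges = attr(dist, "bin_edges"),
                      mids = dist$bin_bp, counts = dist$mass_fg,
                      n_molecules = length(lens), weighted = TRUE),
                 class = "intensity_histogram")
  fit <- fit_gaussian_sum(h, initial_peaks_at(h, neb_1kb_lengths()))
  pops <- population_summary(fit)
  truth_fg <- 2000 * bp_to_fg(neb_1kb_lengths())
  expect_equal(nrow(pops), 10)
  # well-isolated short populations: amounts within 5% individually;
  # partially overlapping long populations trade area between neighbours,
  # so their identifiable quantity is the pairwise mass sum
  rel_err <- (pops$mass_fg - truth_fg) / truth_fg
  expect_lt(max(abs(rel_err[1:4])), 0.05)
  pair_sum_err <- vapply(5:9, function(i) {
    sum(pops$mass_fg[i:(i + 1)]) / sum(truth_fg[i:(i + 1)]) - 1
  }, numeric(1))
  expect_lt(max(abs(pair_sum_err)), 0.05)
  expect_lt(mean(abs(rel_err)), 0.05)
  # total sampled mass equals ground truth within 3%
  expect_equal(sampled_mass(dist), sum(bp_to_fg(rep(neb_1kb_lengths(),
                                                    each = 2000))),
               tolerance = 0.03)
})

test_that("subsampling preserves the size distribution", {
  cfg <- ladder_config(count = 1500L, seed = 19)
  mol <- simulate_molecules(cfg)
  lens <- mol$yoyo_intensity / (2 * exp(0.06^2 / 2))
  full <- subsample_analysis(lens, 1.0, seed = 5,
                             expected_lengths = neb_1kb_lengths())
  frac <- subsample_analysis(lens, c(0.5, 0.25), seed = 5,
                             expected_lengths = neb_1kb_lengths())
  expect_equal(full[["1"]]$n_molecules, length(lens))
  # population lengths stable under subsampling (within 2%)
  for (f in names(frac)) {
    p <- frac[[f]]$populations
    expect_equal(nrow(p), 10)
    expect_lt(max(abs(p$length_bp - full[["1"]]$populations$length_bp) /
                    p$length_bp), 0.02)
  }
  expect_equal(frac[["0.5"]]$sampled_fg / full[["1"]]$sampled_fg, 0.5,
               tolerance = 0.05)
  # starving a population flags it unresolved
  few <- subsample_analysis(c(rnorm(2000, 1000, 50), rnorm(40, 8000, 400)),
                            0.1, seed = 6,
                            expected_lengths = c(1000, 8000))
  expect_true(few[["0.1"]]$populations$unresolved[2])
})

test_that("population length estimates are stable across subsample seeds", {
  cfg <- ladder_config(count = 2000L, seed = 23)
  mol <- simulate_molecules(cfg)
  lens <- mol$yoyo_intensity / (2 * exp(0.06^2 / 2))
  centers <- sapply(1:5, function(s) {
    r <- subsample_analysis(lens, 0.25, seed = s,
                            expected_lengths = neb_1kb_lengths())
    r[["0.25"]]$populations$length_bp
  })
  mean_est <- rowMeans(centers)
  expect_lt(max(abs(mean_est - neb_1kb_lengths()) / neb_1kb_lengths()),
            0.02)
})
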