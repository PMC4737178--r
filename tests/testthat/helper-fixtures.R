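# shared fixtures: built in code at test time, never stored on disk

neb_1kb_lengths <- function() c(0.5, 1, 1.5, 2, 3, 4, 5, 6, 8, 10) * 1000

ladder_config <- function(count = 2000L, intensity_cv = 0.06, seed = 1L,
                          references = FALSE, ref_count = count) {
  refs <- if (references)
    data.frame(length_bp = c(2991, 7029), count = ref_count,
               quench_factor = c(0.910, 0.918))
  sim_config(data.frame(length_bp = neb_1kb_lengths(), count = count),
             reference_populations = refs,
             intensity_cv = intensity_cv, seed = seed)
}

small_optics <- function(...) {
  optics_config(image_shape = c(160L, 160L), seed = 2L, ...)
}

# brute-force windowed median (clamped window, stats::median semantics)
brute_force_median_filter <- function(img, w) {
  r <- w %/% 2
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    out[i, j] <- stats::median(img[max(1, i - r):min(nr, i + r),
                                   max(1, j - r):min(nc, j + r)])
  }
  out
}

# render a set of molecules in one in-memory FOV and detect both channels
render_and_detect <- function(cfg, optics, molecules_per_fov = 250L,
                              params = detection_params()) {
  ds <- simulate_dataset(cfg, optics, out_dir = NULL,
                         molecules_per_fov = molecules_per_fov)
  spots <- do.call(rbind, lapply(seq_along(ds$images), function(f) rbind(
    detect_spots(ds$images[[f]]$yoyo, params, f, "yoyo"),
    detect_spots(ds$images[[f]]$cy5, params, f, "cy5"))))
  list(ground_truth = ds$ground_truth, spots = spots)
}

# nearest ground-truth molecule for each detected yoyo spot
match_to_truth <- function(spots, ground_truth) {
  t(vapply(seq_len(nrow(spots)), function(i) {
    g <- ground_truth[ground_truth$fov == spots$fov[i], ]
    d2 <- (g$x - spots$x[i])^2 + (g$y - spots$y[i])^2
    j <- which.min(d2)
    c(dist = sqrt(d2[j]), yoyo_intensity = g$yoyo_intensity[j],
      is_reference = as.numeric(g$is_reference[j]),
      length_bp = g$length_bp[j])
  }, numeric(4)))
}
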