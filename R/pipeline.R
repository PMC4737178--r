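#' Default run configuration
#'
#' Nested list of every pipeline parameter with its default. A user YAML
#' config only needs the keys it overrides; [validate_config()] fills in the
#' rest and rejects unknown keys. Per-stage RNG seeds are derived from the
#' run seed with fixed offsets (simulation +0, optics +1000, quench
#' calibration simulation +2000, subsampling +3000) so every stage is
#' individually reproducible.
#'
#' @return Nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "smsizer_run",
    simulate = NULL,   # list(populations=, reference_populations=, ...)
    input = list(image_dir = NULL, spots_csv = NULL),
    detect = list(background_window = 31L, threshold_sigmas = 5,
                  min_separation = 5, aperture_radius = 4,
                  max_area_px = 100L, saturation_value = 65535,
                  flatfield = TRUE),
    classify = list(radius = 2.0, estimate_shift = TRUE),
    fit = list(bins = 256L, expected_k = NULL, expected_lengths = NULL,
               weighting = "poisson"),
    calibrate = list(quench = "auto", true_lengths = c(2991, 7029),
                     through_origin = FALSE, ref_count = 10000L),
    quantify = list(bins = 256L, m_bp = 650, mode = "exact"))
}

default_simulate_config <- function() {
  list(populations = NULL, reference_populations = NULL,
       intensity_gain = 2, intensity_cv = 0.06, cy5_level = 800,
       molecules_per_fov = 350L,
       optics = list(image_shape = c(512L, 512L), psf_sigma = 1.3,
                     background_level = 20, illumination = "dome",
                     illum_min = 0.7, read_noise_sigma = 3,
                     shot_noise = TRUE, min_spot_separation = 8,
                     allow_overlaps = FALSE, edge_margin = 8,
                     channel_shift = c(0, 0)))
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.null(user[[nm]])) next # explicit nulls keep the default
    d <- defaults[[nm]]
    if (is.list(d) && !is.null(names(d)) && is.list(user[[nm]])) {
      defaults[[nm]] <- merge_config(d, user[[nm]], paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load, validate and normalize a run configuration
#'
#' Reads a YAML file, fills every missing parameter with its default and
#' rejects unknown keys exhaustively. An empty file yields the full default
#' configuration. The result round-trips unchanged through
#' [write_run_config()] / [validate_config()].
#'
#' @param path YAML file path.
#' @return Normalized configuration list of class `run_config`.
#' @export
validate_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_run_config(), user)
  if (!is.null(cfg$simulate))
    cfg$simulate <- merge_config(default_simulate_config(), cfg$simulate,
                                 "simulate.")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("run_config", "list"))
}

#' @rdname validate_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Quench calibration from a matched synthetic experiment
#'
#' Simulates intensity tables for unlabeled PCR products of the standard
#' lengths and for their Cy5-labeled (quenched) counterparts under the same
#' gain and noise model, fits each two-population histogram with a Gaussian
#' sum, and runs [quench_calibrate()] on the fitted centers. This stands in
#' for the bench calibration experiment when the pipeline is driven end to
#' end on synthetic data.
#'
#' @param true_lengths standard lengths, bp.
#' @param quench_factors YOYO-1 quench factor of each labeled standard.
#' @param intensity_gain,intensity_cv as in [sim_config()].
#' @param count molecules per population; the default pools the equivalent
#'   of several calibration samples, mirroring the bench practice of
#'   averaging the quench calibration over repeated experiments.
#' @param bins histogram bins.
#' @param seed RNG seed.
#' @return A `quench_calibration`.
#' @export
simulate_quench_calibration <- function(true_lengths, quench_factors,
                                        intensity_gain = 2,
                                        intensity_cv = 0.06,
                                        count = 10000L, bins = 256L,
                                        seed = 1L) {
  stopifnot(length(true_lengths) == length(quench_factors))
  fit_two <- function(cfg) {
    mol <- simulate_molecules(cfg)
    h <- make_histogram(mol$yoyo_intensity, binning = bins)
    fit_gaussian_sum(h, initial_peaks(h, expected_k = length(true_lengths)))
  }
  unl <- fit_two(sim_config(
    data.frame(length_bp = true_lengths, count = count),
    intensity_gain = intensity_gain, intensity_cv = intensity_cv,
    seed = seed))
  lab <- fit_two(sim_config(
    data.frame(length_bp = numeric(), count = numeric()),
    reference_populations = data.frame(length_bp = true_lengths,
                                       count = count,
                                       quench_factor = quench_factors),
    intensity_gain = intensity_gain, intensity_cv = intensity_cv,
    seed = seed + 1L))
  quench_calibrate(unl$peaks, lab$peaks, true_lengths)
}

log_line <- function(log_path, ...) {
  cat(paste0(..., "\n"), file = log_path, append = TRUE)
}

#' Run the full sizing assay
#'
#' Orchestrates simulate (optional) -> detect -> classify -> reference fit ->
#' calibrate -> sample fit -> quantify, writing every intermediate artifact
#' (spots, classified molecules, reference peaks, calibration curve, size
#' distribution, population table, summary JSON, run log and figures) into
#' the configured output directory. A stage failure aborts with an error
#' naming the stage; artifacts of completed stages are retained.
#'
#' @param config a `run_config` from [validate_config()], or a path to a
#'   YAML config file.
#' @return Invisibly, a list with `spots`, `molecules`, `curve`,
#'   `distribution`, `populations`, `summary`.
#' @export
run_assay <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  cat("", file = log_path)
  log_line(log_path, "smsizer ", as.character(utils::packageVersion("smsizer")),
           " | seed ", config$seed)
  write_run_config(config, file.path(out_dir, "run_config.yaml"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # --- simulate (optional) ---------------------------------------------
  image_dir <- config$input$image_dir
  if (!is.null(config$simulate)) {
    image_dir <- file.path(out_dir, "images")
    stage("simulate", {
      sc <- config$simulate
      cfg <- sim_config(
        populations = as.data.frame(sc$populations),
        reference_populations = if (is.null(sc$reference_populations)) NULL
        else as.data.frame(sc$reference_populations),
        intensity_gain = sc$intensity_gain, intensity_cv = sc$intensity_cv,
        cy5_level = sc$cy5_level, seed = config$seed)
      oc <- do.call(optics_config,
                    c(sc$optics, list(seed = config$seed + 1000L)))
      simulate_dataset(cfg, oc, image_dir,
                       molecules_per_fov = sc$molecules_per_fov)
      log_line(log_path, "simulate: ",
               sum(unlist(sc$populations$count)) +
                 sum(unlist(sc$reference_populations$count)),
               " molecules written to ", image_dir)
    })
  }

  # --- detect ----------------------------------------------------------
  spots <- stage("detect", {
    if (is.null(image_dir)) {
      if (is.null(config$input$spots_csv))
        stop("no image_dir, spots_csv or simulate block configured")
      utils::read.csv(config$input$spots_csv, stringsAsFactors = FALSE)
    } else {
      dp <- do.call(detection_params, config$detect)
      extract_intensities(image_dir, dp, verbose = FALSE)
    }
  })
  utils::write.csv(spots, file.path(out_dir, "spots.csv"), row.names = FALSE)
  log_line(log_path, "detect: ", sum(spots$channel == "yoyo"), " yoyo / ",
           sum(spots$channel == "cy5"), " cy5 spots; ",
           sum(spots$flagged & spots$channel == "yoyo"), " yoyo flagged")

  # --- classify --------------------------------------------------------
  molecules <- stage("classify", {
    yoyo <- spots[spots$channel == "yoyo" & !spots$flagged, , drop = FALSE]
    cy5 <- spots[spots$channel == "cy5" & !spots$flagged, , drop = FALSE]
    if (nrow(yoyo) == 0) stop("no unflagged yoyo spots to classify")
    shift <- if (isTRUE(config$classify$estimate_shift) && nrow(cy5) >= 10)
      estimate_channel_shift(yoyo, cy5) else c(0, 0)
    log_line(log_path, "classify: channel shift (",
             round(shift[1], 3), ", ", round(shift[2], 3), ") px")
    colocalize(yoyo, cy5, radius = config$classify$radius, shift = shift)
  })
  utils::write.csv(molecules, file.path(out_dir, "molecules.csv"),
                   row.names = FALSE)
  n_ref <- sum(molecules$class == "reference")
  log_line(log_path, "classify: ", n_ref, " reference / ",
           sum(molecules$class == "sample"), " sample molecules")

  # --- reference fit + calibration -------------------------------------
  cal <- stage("calibrate", {
    true_lengths <- sort(unlist(config$calibrate$true_lengths))
    n_std <- length(true_lengths)
    if (n_ref < 10L * n_std)
      stop("missing reference molecules: only ", n_ref,
           " colocalized molecules found (need >= ", 10L * n_std,
           " for ", n_std, " standards); was the reference standard spiked ",
           "in and the Cy5 channel imaged?")
    # keep ~10+ molecules per occupied bin so the peak search sees smooth
    # maxima even for sparse reference sets
    ref_bins <- min(config$fit$bins, max(32L, as.integer(n_ref / 10)))
    rh <- make_histogram(
      molecules$integrated_intensity[molecules$class == "reference"],
      binning = ref_bins)
    rfit <- fit_gaussian_sum(rh, initial_peaks(rh, expected_k = n_std),
                             weighting = config$fit$weighting)
    utils::write.csv(rfit$peaks, file.path(out_dir, "peaks_ref.csv"),
                     row.names = FALSE)
    qc <- config$calibrate$quench
    quench <- if (identical(qc, "auto")) {
      sc <- config$simulate
      if (is.null(sc) || is.null(sc$reference_populations))
        stop("calibrate$quench = 'auto' requires a simulate block with ",
             "reference_populations")
      rp <- as.data.frame(sc$reference_populations)
      simulate_quench_calibration(
        true_lengths = rp$length_bp[order(rp$length_bp)],
        quench_factors = rp$quench_factor[order(rp$length_bp)],
        intensity_gain = sc$intensity_gain, intensity_cv = sc$intensity_cv,
        count = config$calibrate$ref_count, bins = config$fit$bins,
        seed = config$seed + 2000L)
    } else read_quench(qc)
    write_quench(quench, file.path(out_dir, "quench.json"))
    curve <- build_calibration(rfit$peaks$center,
                               quench$standards$imaged_bp,
                               through_origin = config$calibrate$through_origin)
    write_calibration(curve, file.path(out_dir, "curve.json"))
    log_line(log_path, "calibrate: slope ", signif(curve$slope, 6),
             " bp/au, intercept ", signif(curve$intercept, 6), " bp")
    list(curve = curve, quench = quench, ref_fit = rfit)
  })

  # --- sample fit + quantify -------------------------------------------
  result <- stage("quantify", {
    samp <- molecules[molecules$class == "sample", , drop = FALSE]
    lengths <- intensity_to_length(cal$curve, samp$integrated_intensity)
    lengths <- lengths[!is.na(lengths)]
    dist <- size_distribution(lengths, binning = config$quantify$bins,
                              m_bp = config$quantify$m_bp,
                              mode = config$quantify$mode)
    mh <- structure(
      list(bin_edges = attr(dist, "bin_edges"), mids = dist$bin_bp,
           counts = dist$mass_fg, n_molecules = length(lengths),
           weighted = TRUE),
      class = "intensity_histogram")
    init <- if (!is.null(config$fit$expected_lengths))
      initial_peaks_at(mh, unlist(config$fit$expected_lengths))
    else initial_peaks(mh, expected_k = config$fit$expected_k)
    fit <- fit_gaussian_sum(mh, init, weighting = config$fit$weighting)
    pops <- population_summary(fit)
    list(distribution = dist, fit = fit, populations = pops,
         total_fg = sampled_mass(dist), n_sized = length(lengths))
  })
  utils::write.csv(result$distribution,
                   file.path(out_dir, "distribution.csv"), row.names = FALSE)
  utils::write.csv(result$populations,
                   file.path(out_dir, "populations.csv"), row.names = FALSE)
  summary <- list(
    n_yoyo_spots = sum(spots$channel == "yoyo"),
    n_unflagged = sum(spots$channel == "yoyo" & !spots$flagged),
    n_reference = n_ref,
    n_sample_sized = result$n_sized,
    total_sampled_fg = result$total_fg,
    calibration = list(slope_bp_per_au = cal$curve$slope,
                       intercept_bp = cal$curve$intercept),
    seed = config$seed)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(log_path, "quantify: ", result$n_sized, " molecules sized, ",
           signif(result$total_fg, 5), " fg sampled")
  try({
    grDevices::png(file.path(out_dir, "fit.png"), 900, 600)
    plot_mixture_fit(result$fit, xlab = "length (bp)",
                     ylab = "DNA amount (fg/bin)")
    grDevices::dev.off()
    grDevices::png(file.path(out_dir, "populations.png"), 900, 600)
    plot_populations(result$populations)
    grDevices::dev.off()
  }, silent = TRUE)
  invisible(list(spots = spots, molecules = molecules, curve = cal$curve,
                 quench = cal$quench, fit = result$fit,
                 distribution = result$distribution,
                 populations = result$populations, summary = summary))
}

#' Plot a histogram with its fitted Gaussian sum and residuals
#'
#' @param fit a [fit_gaussian_sum()] result.
#' @param xlab,ylab axis labels.
#' @export
plot_mixture_fit <- function(fit, xlab = "intensity (au)",
                             ylab = "molecules/bin") {
  h <- fit$histogram
  graphics::plot(h$mids, h$counts, type = "h", col = "grey60",
                 xlab = xlab, ylab = ylab)
  graphics::lines(h$mids, fit$fitted, col = "black", lwd = 2)
  graphics::lines(h$mids, fit$residuals, col = "steelblue")
  graphics::legend("topright", legend = c("data", "fitted sum", "residual"),
                   col = c("grey60", "black", "steelblue"), lwd = c(1, 2, 1),
                   bty = "n")
  invisible(fit)
}

#' Bar plot of normalized population amounts
#'
#' @param populations a [population_summary()] table.
#' @export
plot_populations <- function(populations) {
  graphics::barplot(populations$normalized_amount,
                    names.arg = round(populations$length_bp),
                    xlab = "population length (bp)",
                    ylab = "normalized amount", col = "darkgreen")
  invisible(populations)
}
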