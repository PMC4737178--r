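#' Simulation configuration for synthetic single-molecule samples
#'
#' Describes the molecular content of a simulated sample: the unknown-sample
#' populations, the Cy5-labeled reference-standard populations, and the
#' intensity model. Per-molecule integrated YOYO-1 intensity follows
#' \eqn{I = g \cdot L \cdot q \cdot e^{\epsilon}}, with gain \eqn{g} (au/bp),
#' length \eqn{L} (bp), quench factor \eqn{q} (1 for unlabeled molecules) and
#' \eqn{\epsilon \sim N(0, \sigma^2)} where \eqn{\sigma} is `intensity_cv`
#' (lognormal multiplicative noise; for small \eqn{\sigma} it equals the
#' coefficient of variation). Intensity spread therefore scales with length,
#' which is what produces the monotonic broadening of histogram peaks with
#' fragment size.
#'
#' @param populations data.frame with columns `length_bp` (positive integer)
#'   and `count` (non-negative integer): the unknown-sample populations.
#' @param reference_populations optional data.frame with columns `length_bp`,
#'   `count` and `quench_factor` in (0, 1]: Cy5-labeled internal standards
#'   whose YOYO-1 intensity is dimmed by the quench factor.
#' @param intensity_gain au of integrated YOYO-1 intensity per base pair.
#' @param intensity_cv lognormal sigma of the per-molecule multiplicative
#'   intensity noise (~ coefficient of variation). The default 0.06 is chosen
#'   so that a standard 10-band 1 kb ladder yields 10 resolvable histogram
#'   peaks, as observed in the real assay; see the methods vignette.
#' @param cy5_level mean integrated Cy5 intensity (au) of a reference
#'   molecule (length-independent; it reflects the number of covalently
#'   attached Cy5 dyes, not intercalation).
#' @param seed integer RNG seed.
#' @return An object of class `sim_config`.
#' @seealso [simulate_molecules()], [simulate_dataset()]
#' @export
sim_config <- function(populations,
                       reference_populations = NULL,
                       intensity_gain = 2,
                       intensity_cv = 0.06,
                       cy5_level = 800,
                       seed = 1L) {
  populations <- as.data.frame(populations)
  stopifnot(all(c("length_bp", "count") %in% names(populations)))
  if (nrow(populations) > 0 && any(populations$length_bp < 1))
    stop("all population lengths must be >= 1 bp")
  if (nrow(populations) > 0 && any(populations$count < 0))
    stop("population counts must be non-negative")
  if (!is.null(reference_populations)) {
    reference_populations <- as.data.frame(reference_populations)
    stopifnot(all(c("length_bp", "count", "quench_factor") %in%
                    names(reference_populations)))
    if (nrow(reference_populations) > 0) {
      if (any(reference_populations$length_bp < 1))
        stop("all population lengths must be >= 1 bp")
      if (any(reference_populations$count < 0))
        stop("population counts must be non-negative")
      q <- reference_populations$quench_factor
      if (any(q <= 0 | q > 1))
        stop("quench_factor must lie in (0, 1]")
    }
  }
  if (!is.numeric(intensity_gain) || intensity_gain <= 0)
    stop("intensity_gain must be positive")
  if (intensity_cv < 0) stop("intensity_cv must be non-negative")
  structure(
    list(populations = populations,
         reference_populations = reference_populations,
         intensity_gain = intensity_gain,
         intensity_cv = intensity_cv,
         cy5_level = cy5_level,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Optical / camera configuration for rendered fields of view
#'
#' @param image_shape integer c(rows, cols) in pixels.
#' @param psf_sigma Gaussian point-spread-function sigma in pixels.
#' @param background_level mean background in au per pixel (before the
#'   illumination field is applied).
#' @param illumination `"dome"` for a low-order polynomial dome peaking at 1
#'   in the center and falling to `illum_min` at the corners, `"flat"` for
#'   uniform illumination, or a user-supplied matrix of the image shape with
#'   values in (0, 1].
#' @param illum_min minimum of the dome illumination field.
#' @param read_noise_sigma Gaussian camera read noise, au per pixel.
#' @param shot_noise logical; apply Poisson shot noise to the expected counts.
#' @param min_spot_separation minimum center-to-center distance (pixels)
#'   enforced when placing molecules (ignored when `allow_overlaps`).
#' @param allow_overlaps logical; place molecules uniformly without the
#'   separation constraint (stress-test mode).
#' @param edge_margin keep molecule centers at least this many pixels away
#'   from the image border.
#' @param channel_shift numeric c(dx, dy): translation (pixels) applied to
#'   the Cy5 channel relative to YOYO-1, to exercise registration.
#' @param seed integer RNG seed for placement and camera noise.
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(image_shape = c(512L, 512L),
                          psf_sigma = 1.3,
                          background_level = 20,
                          illumination = "dome",
                          illum_min = 0.7,
                          read_noise_sigma = 3,
                          shot_noise = TRUE,
                          min_spot_separation = 8,
                          allow_overlaps = FALSE,
                          edge_margin = 8,
                          channel_shift = c(0, 0),
                          seed = 1L) {
  if (psf_sigma <= 0) stop("psf_sigma must be positive")
  if (is.matrix(illumination)) {
    if (!all(dim(illumination) == image_shape))
      stop("illumination matrix must match image_shape")
    if (any(illumination <= 0 | illumination > 1))
      stop("illumination values must lie in (0, 1]")
  } else {
    illumination <- match.arg(illumination, c("dome", "flat"))
  }
  structure(
    list(image_shape = as.integer(image_shape),
         psf_sigma = psf_sigma,
         background_level = background_level,
         illumination = illumination,
         illum_min = illum_min,
         read_noise_sigma = read_noise_sigma,
         shot_noise = isTRUE(shot_noise),
         min_spot_separation = min_spot_separation,
         allow_overlaps = isTRUE(allow_overlaps),
         edge_margin = edge_margin,
         channel_shift = as.numeric(channel_shift),
         seed = as.integer(seed)),
    class = "optics_config")
}

#' Evaluate the illumination field of an optics configuration
#'
#' @param optics an [optics_config()].
#' @return Matrix of the image shape with values in (0, 1].
#' @export
illumination_field <- function(optics) {
  shape <- optics$image_shape
  if (is.matrix(optics$illumination)) return(optics$illumination)
  if (identical(optics$illumination, "flat"))
    return(matrix(1, shape[1], shape[2]))
  # separable quadratic dome: 1 at center, illum_min at the corners
  u <- (seq_len(shape[1]) - (shape[1] + 1) / 2) / ((shape[1] - 1) / 2)
  v <- (seq_len(shape[2]) - (shape[2] + 1) / 2) / ((shape[2] - 1) / 2)
  a <- sqrt(1 - optics$illum_min) # so that (1 - a u^2)(1 - a v^2) >= illum_min
  outer(1 - a * u^2, 1 - a * v^2)
}

#' Draw per-molecule ground truth from a simulation configuration
#'
#' Generates one row per molecule with its true length, reference flag and
#' noisy integrated intensities in both channels. Sample molecules carry zero
#' Cy5 intensity; reference molecules have their YOYO-1 intensity multiplied
#' by the population quench factor.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `length_bp`, `is_reference`,
#'   `quench_factor`, `yoyo_intensity`, `cy5_intensity`.
#' @examples
#' cfg <- sim_config(data.frame(length_bp = 3000, count = 5),
#'                   intensity_cv = 0, intensity_gain = 1)
#' simulate_molecules(cfg)$yoyo_intensity  # exactly 3000 au each
#' @export
simulate_molecules <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pops <- config$populations
  refs <- config$reference_populations
  blocks <- list()
  if (nrow(pops) > 0) {
    blocks[[1]] <- data.frame(
      length_bp = rep(as.integer(pops$length_bp), pops$count),
      is_reference = FALSE,
      quench_factor = 1)
  }
  if (!is.null(refs) && nrow(refs) > 0) {
    blocks[[length(blocks) + 1L]] <- data.frame(
      length_bp = rep(as.integer(refs$length_bp), refs$count),
      is_reference = TRUE,
      quench_factor = rep(refs$quench_factor, refs$count))
  }
  if (length(blocks) == 0 || sum(vapply(blocks, nrow, 1L)) == 0) {
    return(data.frame(length_bp = integer(), is_reference = logical(),
                      quench_factor = numeric(), yoyo_intensity = numeric(),
                      cy5_intensity = numeric()))
  }
  mol <- do.call(rbind, blocks)
  n <- nrow(mol)
  eps <- if (config$intensity_cv > 0)
    exp(stats::rnorm(n, 0, config$intensity_cv)) else rep(1, n)
  mol$yoyo_intensity <- config$intensity_gain * mol$length_bp *
    mol$quench_factor * eps
  cy5 <- rep(0, n)
  nref <- sum(mol$is_reference)
  if (nref > 0) {
    cy5eps <- if (config$intensity_cv > 0)
      exp(stats::rnorm(nref, 0, config$intensity_cv)) else rep(1, nref)
    cy5[mol$is_reference] <- config$cy5_level * cy5eps
  }
  mol$cy5_intensity <- cy5
  rownames(mol) <- NULL
  mol
}

# Rejection-sample n positions inside one FOV honoring min separation.
# Returns data.frame(x, y) in 0-based pixel coordinates (pixel centers at
# integers).
place_positions <- function(n, optics) {
  shape <- optics$image_shape
  m <- optics$edge_margin
  lo_x <- m; hi_x <- shape[2] - 1 - m
  lo_y <- m; hi_y <- shape[1] - 1 - m
  if (hi_x <= lo_x || hi_y <= lo_y) stop("image too small for edge_margin")
  if (n == 0) return(data.frame(x = numeric(), y = numeric()))
  if (optics$allow_overlaps) {
    return(data.frame(x = stats::runif(n, lo_x, hi_x),
                      y = stats::runif(n, lo_y, hi_y)))
  }
  sep2 <- optics$min_spot_separation^2
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L
  attempts <- 0L; max_attempts <- 500L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not place ", n, " molecules at the requested separation; ",
           "reduce molecules per FOV or min_spot_separation")
    x <- stats::runif(1, lo_x, hi_x); y <- stats::runif(1, lo_y, hi_y)
    if (placed > 0L) {
      d2 <- (xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2
      if (min(d2) < sep2) next
    }
    placed <- placed + 1L
    xs[placed] <- x; ys[placed] <- y
  }
  data.frame(x = xs, y = ys)
}

# Add pixel-integrated Gaussian spots to `img` (modified copy returned).
add_spots <- function(img, x, y, intensity, psf_sigma) {
  if (length(x) == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  r <- ceiling(6 * psf_sigma) + 1L
  for (i in seq_along(x)) {
    cx <- x[i]; cy <- y[i]
    # 0-based coordinates; matrix row = y + 1, col = x + 1
    jx <- max(0, floor(cx) - r):min(nc - 1, ceiling(cx) + r)
    jy <- max(0, floor(cy) - r):min(nr - 1, ceiling(cy) + r)
    fx <- stats::pnorm(jx + 0.5, cx, psf_sigma) -
      stats::pnorm(jx - 0.5, cx, psf_sigma)
    fy <- stats::pnorm(jy + 0.5, cy, psf_sigma) -
      stats::pnorm(jy - 0.5, cy, psf_sigma)
    img[jy + 1L, jx + 1L] <- img[jy + 1L, jx + 1L] +
      intensity[i] * outer(fy, fx)
  }
  img
}

#' Render one two-channel field of view
#'
#' Each molecule becomes a pixel-integrated 2-D Gaussian spot whose total
#' (background-free, illumination-free) counts equal its channel intensity.
#' The expected image is `illumination * (background_level + signal)`; Poisson
#' shot noise and Gaussian read noise are then applied. Reference molecules
#' appear in both channels at the same coordinates (up to the configured
#' channel shift). Molecules outside the image bounds are dropped with a
#' warning.
#'
#' @param molecules data.frame with columns `x`, `y` (0-based pixel
#'   coordinates), `yoyo_intensity`, `cy5_intensity`.
#' @param optics an [optics_config()].
#' @param seed optional RNG seed overriding `optics$seed` for the camera
#'   noise of this FOV.
#' @return list with matrices `yoyo` and `cy5`.
#' @export
render_fov <- function(molecules, optics, seed = NULL) {
  stopifnot(inherits(optics, "optics_config"))
  shape <- optics$image_shape
  inb <- molecules$x >= 0 & molecules$x <= shape[2] - 1 &
    molecules$y >= 0 & molecules$y <= shape[1] - 1
  if (any(!inb)) {
    warning(sum(!inb), " molecule(s) outside image bounds rejected")
    molecules <- molecules[inb, , drop = FALSE]
  }
  illum <- illumination_field(optics)
  set.seed(if (is.null(seed)) optics$seed else seed)
  render_one <- function(intensity, shift) {
    sig <- matrix(0, shape[1], shape[2])
    keep <- intensity > 0
    sig <- add_spots(sig, molecules$x[keep] + shift[1],
                     molecules$y[keep] + shift[2],
                     intensity[keep], optics$psf_sigma)
    expected <- illum * (optics$background_level + sig)
    img <- if (optics$shot_noise)
      matrix(stats::rpois(length(expected), expected), shape[1], shape[2])
    else expected
    if (optics$read_noise_sigma > 0)
      img <- img + matrix(stats::rnorm(length(img), 0,
                                       optics$read_noise_sigma),
                          shape[1], shape[2])
    pmax(img, 0)
  }
  list(yoyo = render_one(molecules$yoyo_intensity, c(0, 0)),
       cy5 = render_one(molecules$cy5_intensity, optics$channel_shift))
}

#' Simulate a full multi-FOV dataset and write it to disk
#'
#' Draws molecules from `config`, distributes them over fields of view at
#' random positions (respecting the minimum spot separation), renders each
#' FOV in both channels, and writes 16-bit grayscale TIFFs
#' (`fov{NNN}_yoyo.tif`, `fov{NNN}_cy5.tif`) plus `ground_truth.csv`.
#'
#' @param config a [sim_config()].
#' @param optics an [optics_config()].
#' @param out_dir output directory (created if missing). `NULL` skips writing
#'   and returns the images in memory.
#' @param molecules_per_fov target number of molecules per field of view.
#' @return Invisibly, a list with `ground_truth` (data.frame with columns
#'   `fov,x,y,length_bp,is_reference,yoyo_intensity,cy5_intensity`) and,
#'   when `out_dir` is `NULL`, `images` (list of per-FOV channel pairs).
#' @export
simulate_dataset <- function(config, optics, out_dir = NULL,
                             molecules_per_fov = 350L) {
  stopifnot(inherits(config, "sim_config"), inherits(optics, "optics_config"))
  mol <- simulate_molecules(config)
  n <- nrow(mol)
  set.seed(config$seed + 1L)
  if (n > 0) mol <- mol[sample.int(n), , drop = FALSE] # mix populations
  n_fov <- max(1L, ceiling(n / molecules_per_fov))
  fov_id <- rep(seq_len(n_fov), length.out = n)
  keep_images <- is.null(out_dir)
  if (!keep_images) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  images <- if (keep_images) vector("list", n_fov) else NULL
  gt <- vector("list", n_fov)
  for (f in seq_len(n_fov)) {
    mf <- mol[fov_id == f, , drop = FALSE]
    set.seed(optics$seed + 7919L * f)
    pos <- place_positions(nrow(mf), optics)
    mf$x <- pos$x; mf$y <- pos$y
    imgs <- render_fov(mf, optics, seed = optics$seed + 7919L * f + 1L)
    if (keep_images) {
      images[[f]] <- imgs
    } else {
      write_fov_tiff(imgs$yoyo, file.path(out_dir,
                                          sprintf("fov%03d_yoyo.tif", f)))
      write_fov_tiff(imgs$cy5, file.path(out_dir,
                                         sprintf("fov%03d_cy5.tif", f)))
    }
    mf$fov <- f
    gt[[f]] <- mf[, c("fov", "x", "y", "length_bp", "is_reference",
                      "yoyo_intensity", "cy5_intensity")]
  }
  ground_truth <- do.call(rbind, gt)
  rownames(ground_truth) <- NULL
  if (!keep_images)
    write_ground_truth(ground_truth, file.path(out_dir, "ground_truth.csv"))
  invisible(list(ground_truth = ground_truth, images = images))
}

#' Write / read a 16-bit grayscale TIFF field of view
#'
#' Values are clamped to \[0, 65535\] and rounded to integer gray levels on
#' write; [read_fov_tiff()] returns them on the original au scale.
#'
#' @param img numeric matrix (au).
#' @param path file path.
#' @export
write_fov_tiff <- function(img, path) {
  img <- pmin(pmax(img, 0), 65535)
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_fov_tiff
#' @export
read_fov_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img * 65535
}

#' Write / read a molecule ground-truth table
#'
#' The CSV round-trips exactly: numeric columns are written with 17
#' significant digits so `read_ground_truth()` restores identical doubles.
#'
#' @param molecules ground-truth data.frame.
#' @param path CSV path.
#' @export
write_ground_truth <- function(molecules, path) {
  out <- molecules
  for (nm in names(out)) {
    if (is.double(out[[nm]]))
      out[[nm]] <- formatC(out[[nm]], digits = 17, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  gt <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in intersect(c("x", "y", "quench_factor", "yoyo_intensity",
                         "cy5_intensity"), names(gt)))
    gt[[nm]] <- as.double(gt[[nm]])
  for (nm in intersect(c("fov", "length_bp"), names(gt)))
    gt[[nm]] <- as.integer(gt[[nm]])
  gt
}
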