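#' Detection parameters
#'
#' @param background_window odd window (pixels) of the moving-median local
#'   background filter; must be much larger than the PSF extent.
#' @param threshold_sigmas detection threshold in robust (MAD-based) standard
#'   deviations of the background-subtracted image.
#' @param min_separation minimum distance (pixels) between detected maxima;
#'   of two closer candidates the brighter survives.
#' @param aperture_radius radius (pixels) of the circular photometry
#'   aperture; should be at least ~3 PSF sigmas so the aperture captures
#'   essentially all of the spot flux.
#' @param max_area_px spots whose above-threshold footprint exceeds this many
#'   pixels are flagged `oversized` (aggregates, dust).
#' @param saturation_value au at or above which a pixel counts as saturated.
#' @param flatfield logical; correct integrated intensities for uneven
#'   illumination using the normalized local-background map (the smooth
#'   background is proportional to the illumination field, so dividing by
#'   its normalized value at the spot undoes the illumination falloff).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(background_window = 31L,
                             threshold_sigmas = 5,
                             min_separation = 5,
                             aperture_radius = 4,
                             max_area_px = 100L,
                             saturation_value = 65535,
                             flatfield = TRUE) {
  if (background_window %% 2 == 0 || background_window < 3)
    stop("background_window must be an odd integer >= 3")
  if (aperture_radius <= 0) stop("aperture_radius must be positive")
  structure(
    list(background_window = as.integer(background_window),
         threshold_sigmas = threshold_sigmas,
         min_separation = min_separation,
         aperture_radius = aperture_radius,
         max_area_px = as.integer(max_area_px),
         saturation_value = saturation_value,
         flatfield = isTRUE(flatfield)),
    class = "detection_params")
}

#' Estimate the smooth local background of a field of view
#'
#' Moving-median filter: the median over a square window is insensitive to
#' isolated diffraction-limited spots (which occupy a small fraction of the
#' window), so the result tracks the smooth background, including uneven
#' illumination. At the borders the window is clamped to the image.
#'
#' @param image numeric matrix.
#' @param background_window odd window size in pixels, smaller than both
#'   image dimensions.
#' @return Matrix of per-pixel background estimates (au).
#' @export
estimate_local_background <- function(image, background_window = 31L) {
  stopifnot(is.matrix(image))
  median_filter_cpp(image, as.integer(background_window))
}

# local maxima of a matrix: strictly greater than or equal to 8 neighbours
# and strictly greater than at least one (excludes flat regions), with value
# above `floor`
local_maxima <- function(img, floor_value) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 3 || nc < 3) return(cbind(row = integer(), col = integer()))
  core <- img[2:(nr - 1), 2:(nc - 1)]
  ge <- core >= img[1:(nr - 2), 2:(nc - 1)] &
    core >= img[3:nr, 2:(nc - 1)] &
    core >= img[2:(nr - 1), 1:(nc - 2)] &
    core >= img[2:(nr - 1), 3:nc] &
    core >= img[1:(nr - 2), 1:(nc - 2)] &
    core >= img[1:(nr - 2), 3:nc] &
    core >= img[3:nr, 1:(nc - 2)] &
    core >= img[3:nr, 3:nc]
  gt <- core > img[1:(nr - 2), 2:(nc - 1)] |
    core > img[3:nr, 2:(nc - 1)] |
    core > img[2:(nr - 1), 1:(nc - 2)] |
    core > img[2:(nr - 1), 3:nc]
  hit <- which(ge & gt & core > floor_value, arr.ind = TRUE)
  cbind(row = hit[, 1] + 1L, col = hit[, 2] + 1L)
}

#' Detect single-molecule spots in one channel image
#'
#' Subtracts the moving-median local background, finds local maxima exceeding
#' `threshold_sigmas` robust standard deviations (1.4826 x MAD of the
#' background-subtracted image), merges maxima closer than `min_separation`
#' (keeping the brighter), and measures each spot by a fixed circular
#' aperture sum of background-subtracted counts, with an intensity-weighted
#' sub-pixel centroid. Spots touching the border, containing saturated
#' pixels, or with an oversized above-threshold footprint are flagged; flagged
#' spots should be excluded from downstream statistics (see `flagged`).
#'
#' Coordinates are 0-based with pixel centers at integers (`x` = column,
#' `y` = row).
#'
#' @param image numeric matrix (au).
#' @param params a [detection_params()].
#' @param fov_id identifier copied into the output.
#' @param channel `"yoyo"` or `"cy5"`.
#' @return data.frame with columns `fov`, `channel`, `x`, `y`,
#'   `integrated_intensity`, `local_background`, `area_px`, `edge`,
#'   `saturated`, `oversized`, `flagged`.
#' @export
detect_spots <- function(image, params = detection_params(),
                         fov_id = 1L, channel = "yoyo") {
  stopifnot(is.matrix(image), inherits(params, "detection_params"))
  empty <- data.frame(
    fov = integer(), channel = character(), x = numeric(), y = numeric(),
    integrated_intensity = numeric(), local_background = numeric(),
    area_px = integer(), edge = logical(), saturated = logical(),
    oversized = logical(), flagged = logical())
  bg <- estimate_local_background(image, params$background_window)
  sub <- image - bg
  # robust noise scale of the background-subtracted image; the quantile
  # fallback covers noise-free synthetic frames where most residuals are 0
  sigma <- stats::mad(sub)
  if (sigma == 0)
    sigma <- stats::quantile(abs(sub), 0.9, names = FALSE) / 1.2816
  if (is.na(sigma) || sigma == 0) sigma <- .Machine$double.eps
  thr <- params$threshold_sigmas * sigma
  mx <- local_maxima(sub, thr)
  if (nrow(mx) == 0) return(empty)

  # enforce min_separation: brighter candidate wins
  vals <- sub[mx]
  ord <- order(-vals, mx[, 1], mx[, 2])
  mx <- mx[ord, , drop = FALSE]; vals <- vals[ord]
  keep <- rep(TRUE, nrow(mx))
  sep2 <- params$min_separation^2
  for (i in seq_len(nrow(mx))) {
    if (!keep[i]) next
    if (i < nrow(mx)) {
      j <- (i + 1):nrow(mx)
      d2 <- (mx[j, 1] - mx[i, 1])^2 + (mx[j, 2] - mx[i, 2])^2
      keep[j][d2 < sep2] <- FALSE
    }
  }
  mx <- mx[keep, , drop = FALSE]

  nr <- nrow(image); nc <- ncol(image)
  r <- params$aperture_radius
  ri <- ceiling(r)
  # Flat-field model: the smooth background is proportional to the
  # illumination field, so a tensor-product quadratic surface fitted to the
  # background map (which spans separable vignetting domes exactly) gives
  # the relative illumination. Correction is skipped when the fitted field
  # is flat to within 5%, so constant frames (and constant offsets on them)
  # are left untouched.
  illum_at <- NULL
  if (params$flatfield) {
    gr <- seq(1, nr, by = 4L); gc <- seq(1, nc, by = 4L)
    g <- expand.grid(row = gr, col = gc)
    basis <- function(row, col) {
      u <- row / nr; v <- col / nc
      cbind(1, u, u^2, v, v^2, u * v, u^2 * v, u * v^2, u^2 * v^2)
    }
    X <- basis(g$row, g$col)
    cf <- qr.coef(qr(X), bg[cbind(g$row, g$col)])
    fitted <- drop(X %*% cf)
    top <- max(fitted)
    if (top > 0 && min(fitted) > 0 && top / min(fitted) > 1.05) {
      illum_at <- function(row, col)
        pmax(drop(basis(row, col) %*% cf) / top, 0.1)
    }
  }
  n <- nrow(mx)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    row0 <- mx[i, 1]; col0 <- mx[i, 2]
    edge <- row0 - ri < 1 || row0 + ri > nr || col0 - ri < 1 || col0 + ri > nc
    rows <- max(1, row0 - ri):min(nr, row0 + ri)
    cols <- max(1, col0 - ri):min(nc, col0 + ri)
    patch <- sub[rows, cols, drop = FALSE]
    # pixel-center distances from the integer maximum
    dy <- rows - row0; dx <- cols - col0
    inap <- outer(dy^2, dx^2, "+") <= r^2
    w <- pmax(patch, 0) * inap
    sw <- sum(w)
    # 0-based sub-pixel centroid
    cy <- (row0 - 1) + if (sw > 0) sum(w * dy) / sw else 0
    cx <- (col0 - 1) + if (sw > 0) sum(outer(rep(1, length(dy)), dx) * w) / sw else 0
    raw <- sum(patch[inap])
    area <- sum(patch[inap] > thr)
    sat <- any(image[rows, cols][inap] >= params$saturation_value)
    corr <- if (!is.null(illum_at)) illum_at(row0, col0) else 1
    res[[i]] <- data.frame(
      fov = fov_id, channel = channel, x = cx, y = cy,
      integrated_intensity = raw / corr,
      local_background = bg[row0, col0],
      area_px = as.integer(area),
      edge = edge, saturated = sat,
      oversized = area > params$max_area_px)
  }
  out <- do.call(rbind, res)
  out$flagged <- out$edge | out$saturated | out$oversized |
    out$integrated_intensity <= 0
  rownames(out) <- NULL
  out
}

#' Detect spots in every field of view of a directory
#'
#' Scans `image_dir` for TIFF pairs named `fov{NNN}_yoyo.tif` /
#' `fov{NNN}_cy5.tif`, runs [detect_spots()] on both channels of each FOV and
#' concatenates the results. FOVs missing one channel are skipped with a
#' warning. Per-FOV detection counts are reported via `message()`.
#'
#' @param image_dir directory containing the TIFF pairs.
#' @param params a [detection_params()].
#' @param verbose logical; emit per-FOV counts.
#' @return Spot data.frame as in [detect_spots()] (possibly empty).
#' @export
extract_intensities <- function(image_dir, params = detection_params(),
                                verbose = TRUE) {
  files <- list.files(image_dir, pattern = "^fov[0-9]+_(yoyo|cy5)\\.tif$")
  ids <- unique(sub("^fov([0-9]+)_.*$", "\\1", files))
  out <- list()
  for (id in sort(ids)) {
    fy <- file.path(image_dir, sprintf("fov%s_yoyo.tif", id))
    fc <- file.path(image_dir, sprintf("fov%s_cy5.tif", id))
    if (!file.exists(fy) || !file.exists(fc)) {
      warning("FOV ", id, " is missing a channel file; skipped")
      next
    }
    fid <- as.integer(id)
    sy <- detect_spots(read_fov_tiff(fy), params, fov_id = fid,
                       channel = "yoyo")
    sc <- detect_spots(read_fov_tiff(fc), params, fov_id = fid,
                       channel = "cy5")
    if (verbose)
      message(sprintf("fov %s: %d yoyo, %d cy5 spots", id, nrow(sy),
                      nrow(sc)))
    out[[length(out) + 1L]] <- rbind(sy, sc)
  }
  if (length(out) == 0) {
    return(data.frame(
      fov = integer(), channel = character(), x = numeric(), y = numeric(),
      integrated_intensity = numeric(), local_background = numeric(),
      area_px = integer(), edge = logical(), saturated = logical(),
      oversized = logical(), flagged = logical()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
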