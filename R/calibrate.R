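#' Quench calibration: effective imaged lengths of Cy5-labeled standards
#'
#' Cy5 labels quench YOYO-1 emission, so a labeled standard looks shorter
#' than an unlabeled molecule of the same length. Fitting the unlabeled
#' intensity histogram gives peak centers whose known true lengths define a
#' line (length vs. center); mapping the labeled peak centers through that
#' line yields each standard's effective apparent length, its *imaged
#' length*, which replaces the true length whenever the labeled standard is
#' later used as an internal calibrator.
#'
#' Peaks are matched to true lengths by rank order of their centers.
#' Uncertainties are propagated from the peak center standard errors by the
#' delta method (numeric gradient).
#'
#' @param unlabeled_peaks,labeled_peaks data.frames with columns `center`
#'   and optionally `center_se` (e.g. the `peaks` of a [fit_gaussian_sum()]),
#'   or bare numeric vectors of centers; equal numbers (>= 2) of peaks.
#' @param true_lengths known standard lengths in bp.
#' @return Object of class `quench_calibration`: data.frame `standards` with
#'   columns `true_bp`, `unlabeled_center`, `labeled_center`, `imaged_bp`,
#'   `imaged_bp_se`.
#' @export
quench_calibrate <- function(unlabeled_peaks, labeled_peaks, true_lengths) {
  as_pk <- function(p) {
    if (is.numeric(p)) data.frame(center = p, center_se = 0)
    else {
      stopifnot("center" %in% names(p))
      if (is.null(p$center_se)) p$center_se <- 0
      p[, c("center", "center_se")]
    }
  }
  u <- as_pk(unlabeled_peaks); l <- as_pk(labeled_peaks)
  if (nrow(u) != nrow(l) || nrow(u) != length(true_lengths))
    stop("unlabeled peaks, labeled peaks and true_lengths must have ",
         "matching counts")
  if (nrow(u) < 2) stop("at least two standards are required")
  u <- u[order(u$center), ]; l <- l[order(l$center), ]
  true_lengths <- sort(true_lengths)
  u$center_se[is.na(u$center_se)] <- 0
  l$center_se[is.na(l$center_se)] <- 0

  imaged_fn <- function(uc, lc) {
    cf <- stats::coef(stats::lm(true_lengths ~ uc))
    cf[1] + cf[2] * lc
  }
  imaged <- imaged_fn(u$center, l$center)
  # delta method over all uncertain centers
  se2 <- rep(0, length(imaged))
  h <- pmax(abs(c(u$center, l$center)), 1) * 1e-6
  for (j in seq_len(nrow(u))) {
    du <- u$center; du[j] <- du[j] + h[j]
    g <- (imaged_fn(du, l$center) - imaged) / h[j]
    se2 <- se2 + (g * u$center_se[j])^2
    dl <- l$center; dl[j] <- dl[j] + h[nrow(u) + j]
    g <- (imaged_fn(u$center, dl) - imaged) / h[nrow(u) + j]
    se2 <- se2 + (g * l$center_se[j])^2
  }
  standards <- data.frame(
    true_bp = true_lengths,
    unlabeled_center = u$center,
    labeled_center = l$center,
    imaged_bp = as.numeric(imaged),
    imaged_bp_se = sqrt(se2))
  if (any(standards$imaged_bp > standards$true_bp))
    warning("imaged length exceeds true length for at least one standard; ",
            "quenching should dim, not brighten")
  structure(list(standards = standards), class = "quench_calibration")
}

#' Persist / load a quench calibration as JSON
#'
#' Schema: `{"standards": [{"true_bp": ..., "imaged_bp": ...,
#' "imaged_bp_se": ...}, ...]}`. The package ships a default calibration for
#' the 2991 / 7029 bp standards (imaged lengths 2721 +- 106 and 6456 +- 82
#' bp) in `inst/extdata/quench_default.json`.
#'
#' @param qc a `quench_calibration` (or a bare `standards` data.frame).
#' @param path JSON file path.
#' @export
write_quench <- function(qc, path) {
  standards <- if (inherits(qc, "quench_calibration")) qc$standards else qc
  keep <- intersect(c("true_bp", "imaged_bp", "imaged_bp_se"),
                    names(standards))
  jsonlite::write_json(list(standards = standards[, keep]), path,
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_quench
#' @export
read_quench <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(is.data.frame(obj$standards),
            all(c("true_bp", "imaged_bp") %in% names(obj$standards)))
  structure(list(standards = obj$standards), class = "quench_calibration")
}

#' Build the per-run intensity-to-length calibration curve
#'
#' With exactly two reference points the line interpolates them exactly; with
#' three or more it is an ordinary least-squares fit of length on center.
#' Centers are matched to imaged lengths by rank order (smaller center means
#' shorter standard); non-monotone pairings and non-positive slopes are
#' errors. The line carries a free intercept by default — the imaging chain
#' can add a length-independent offset — with a through-origin option.
#'
#' @param centers fitted reference peak centers (au).
#' @param imaged_lengths imaged lengths (bp) of the same standards.
#' @param through_origin logical; force a zero intercept.
#' @return Object of class `calibration_curve`: list with `slope` (bp/au),
#'   `intercept` (bp), `points`, `r_squared` (NA for the exact two-point
#'   case).
#' @export
build_calibration <- function(centers, imaged_lengths,
                              through_origin = FALSE) {
  if (length(centers) != length(imaged_lengths) || length(centers) < 2)
    stop("need >= 2 matched (center, imaged_length) points")
  ord <- order(centers)
  x <- centers[ord]; yl <- sort(imaged_lengths)
  if (any(diff(x) <= 0))
    stop("reference peak centers must be distinct")
  if (any(diff(yl) <= 0))
    stop("imaged lengths must be strictly increasing with peak center")
  if (through_origin) {
    slope <- sum(x * yl) / sum(x * x)
    intercept <- 0
    fitted <- slope * x
  } else if (length(x) == 2) {
    slope <- (yl[2] - yl[1]) / (x[2] - x[1])
    intercept <- yl[1] - slope * x[1]
    fitted <- slope * x + intercept
  } else {
    cf <- stats::coef(stats::lm(yl ~ x))
    intercept <- cf[[1]]; slope <- cf[[2]]
    fitted <- slope * x + intercept
  }
  if (slope <= 0) stop("calibration slope must be positive")
  ss_res <- sum((yl - fitted)^2); ss_tot <- sum((yl - mean(yl))^2)
  structure(
    list(slope = slope, intercept = intercept,
         points = data.frame(center = x, imaged_bp = yl),
         r_squared = if (length(x) > 2 && ss_tot > 0) 1 - ss_res / ss_tot
         else NA_real_),
    class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration: length = %.5g bp/au * I + %.5g bp (%d points)\n",
              x$slope, x$intercept, nrow(x$points)))
  invisible(x)
}

#' Persist / load a calibration curve as JSON
#' @param curve a `calibration_curve`.
#' @param path JSON file path.
#' @export
write_calibration <- function(curve, path) {
  jsonlite::write_json(
    list(slope = curve$slope, intercept = curve$intercept,
         points = curve$points, r_squared = curve$r_squared),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(slope = obj$slope, intercept = obj$intercept,
                 points = as.data.frame(obj$points),
                 r_squared = if (is.null(obj$r_squared)) NA_real_
                 else obj$r_squared),
            class = "calibration_curve")
}

#' Convert molecule intensities to lengths in base pairs
#'
#' Applies `length = slope * I + intercept`. Conversions yielding
#' non-positive lengths are returned as `NA` (they cannot be physical
#' molecules) and their count is reported via `message()`.
#'
#' @param curve a `calibration_curve`.
#' @param intensities numeric vector (au).
#' @return Numeric vector of lengths (bp) with `NA` for flagged values.
#' @export
intensity_to_length <- function(curve, intensities) {
  stopifnot(inherits(curve, "calibration_curve"))
  len <- curve$slope * intensities + curve$intercept
  bad <- len <= 0
  if (any(bad)) {
    message(sum(bad), " molecule(s) converted to non-positive length; ",
            "flagged as NA and excluded")
    len[bad] <- NA_real_
  }
  len
}
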