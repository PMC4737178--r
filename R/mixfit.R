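#' Build an intensity (or length) histogram
#'
#' @param values numeric vector (au intensities or bp lengths); must be
#'   non-empty and finite.
#' @param weights optional per-value weights (e.g. femtogram masses); when
#'   given, the histogram accumulates weights instead of counts ("mass
#'   mode").
#' @param binning `"fd"` for the Freedman-Diaconis rule, a single integer
#'   for a fixed number of equal-width bins, or a numeric vector of strictly
#'   increasing bin edges. Mixture analysis of strongly multimodal intensity
#'   data typically needs finer bins than Freedman-Diaconis produces; the
#'   pipeline uses 256 bins by default (see the methods vignette).
#' @return Object of class `intensity_histogram`: list with `bin_edges`,
#'   `mids`, `counts`, `n_molecules`, `weighted`.
#' @export
make_histogram <- function(values, weights = NULL, binning = "fd") {
  if (length(values) == 0) stop("values must be non-empty")
  if (!all(is.finite(values))) stop("values must be finite")
  if (!is.null(weights) && length(weights) != length(values))
    stop("weights must match values in length")
  rng <- range(values)
  if (is.character(binning)) {
    binning <- match.arg(binning, "fd")
    n <- length(values)
    h <- 2 * stats::IQR(values) / n^(1 / 3)
    if (h <= 0) h <- 1
    nb <- max(1L, ceiling(diff(rng) / h))
    edges <- seq(rng[1], rng[1] + nb * h, length.out = nb + 1L)
  } else if (length(binning) == 1L) {
    nb <- as.integer(binning)
    if (nb < 1) stop("number of bins must be >= 1")
    edges <- if (diff(rng) > 0) seq(rng[1], rng[2], length.out = nb + 1L)
    else seq(rng[1] - 0.5, rng[1] + 0.5, length.out = nb + 1L)
  } else {
    edges <- as.numeric(binning)
    if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
    if (rng[1] < edges[1] || rng[2] > edges[length(edges)])
      stop("values fall outside the supplied bin edges")
  }
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  nb <- length(edges) - 1L
  idx[idx > nb] <- nb
  if (is.null(weights)) {
    counts <- tabulate(idx, nbins = nb)
  } else {
    counts <- numeric(nb)
    agg <- rowsum(weights, idx)
    counts[as.integer(rownames(agg))] <- agg
  }
  structure(
    list(bin_edges = edges,
         mids = (edges[-1] + edges[-length(edges)]) / 2,
         counts = as.numeric(counts),
         n_molecules = length(values),
         weighted = !is.null(weights)),
    class = "intensity_histogram")
}

# centered moving average, window w (odd); shrinks at the borders
smooth_counts <- function(y, w) {
  n <- length(y)
  half <- w %/% 2
  vapply(seq_len(n), function(i) {
    j <- max(1, i - half):min(n, i + half)
    mean(y[j])
  }, numeric(1))
}

# indices of local maxima of y (plateau-tolerant, boundaries included: a
# population peak can sit in the first or last bins of the histogram)
find_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer())
  out <- integer()
  if (y[1] > y[2]) out <- 1L
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j <= n - 1L && y[j + 1L] < y[j]) {
        out <- c(out, as.integer(floor((i + j) / 2)))
        i <- j + 1L
        next
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  if (y[n] > y[n - 1L]) out <- c(out, n)
  out
}

# topographic prominence of each maximum: height minus the higher of the two
# key saddles (minimum on the path to the nearest higher maximum, or to the
# data boundary)
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    h <- y[p]
    left <- if (p > 1) {
      seg <- y[1:(p - 1)]
      higher <- which(seg > h)
      if (length(higher) > 0) min(seg[(max(higher) + 1):(p - 1)]) else min(seg)
    } else -Inf
    right <- if (p < length(y)) {
      seg <- y[(p + 1):length(y)]
      higher <- which(seg > h)
      if (length(higher) > 0) min(seg[1:(min(higher) - 1)]) else min(seg)
    } else -Inf
    base <- max(left, right)
    if (!is.finite(base)) base <- 0
    h - base
  }, numeric(1))
}

#' Initial peak parameters from a histogram
#'
#' Finds candidate peaks as local maxima of the smoothed histogram. In
#' automatic mode a maximum is kept when its topographic prominence exceeds
#' `prominence_sigmas` times the local Poisson noise scale of the smoothed
#' counts; the number of surviving maxima defines K. When `expected_k` is
#' given, the K most prominent maxima are used (an error is raised if fewer
#' exist).
#' Initial widths come from the half-width at half maximum of each peak;
#' initial amplitudes from the smoothed height.
#'
#' @param histogram an [make_histogram()] result with at least `3 * K` bins.
#' @param expected_k number of components known from the sample design, or
#'   `NULL` for automatic detection.
#' @param smooth_bins moving-average window (bins) applied before the maximum
#'   search.
#' @param prominence_sigmas automatic-mode prominence threshold in local
#'   noise units.
#' @return data.frame with columns `center`, `sigma`, `amplitude`, ordered
#'   by center.
#' @export
initial_peaks <- function(histogram, expected_k = NULL, smooth_bins = 5L,
                          prominence_sigmas = 5) {
  stopifnot(inherits(histogram, "intensity_histogram"))
  y <- histogram$counts
  x <- histogram$mids
  sm <- smooth_counts(y, smooth_bins)
  peaks <- find_maxima(sm)
  if (length(peaks) == 0) stop("no local maxima found in histogram")
  # merge maxima closer than the smoothing window (noise twins on one peak),
  # keeping the taller; ties resolved toward the left maximum
  if (length(peaks) > 1) {
    ord <- order(-sm[peaks], peaks)
    keep <- rep(TRUE, length(peaks))
    for (i in seq_along(ord)) {
      if (!keep[ord[i]]) next
      close_by <- abs(peaks - peaks[ord[i]]) <= smooth_bins &
        seq_along(peaks) != ord[i]
      keep[close_by & sm[peaks] <= sm[peaks[ord[i]]]] <- FALSE
    }
    peaks <- peaks[keep]
  }
  prom <- peak_prominence(sm, peaks)
  if (is.null(expected_k)) {
    # local Poisson noise of the smoothed counts around each peak's saddle
    ref <- pmax((sm[peaks] + (sm[peaks] - prom)) / 2, 1)
    noise <- sqrt(ref / smooth_bins)
    keep <- prom >= prominence_sigmas * noise
    peaks <- peaks[keep]; prom <- prom[keep]
    if (length(peaks) == 0) stop("no peaks exceed the prominence threshold")
  } else {
    k <- as.integer(expected_k)
    if (length(histogram$counts) < 3L * k)
      stop("histogram has fewer than 3*K bins; rebin more finely")
    if (length(peaks) < k)
      stop("found only ", length(peaks), " local maxima but expected_k = ",
           k)
    # rank by topographic prominence: plain height would prefer noise bumps
    # on the shoulder of a tall peak over genuinely smaller distant peaks
    ord <- order(-prom)
    peaks <- peaks[ord[seq_len(k)]]
  }
  peaks <- sort(peaks)
  w <- mean(diff(histogram$bin_edges))
  sigma <- vapply(peaks, function(p) {
    h <- sm[p]
    li <- p; while (li > 1 && sm[li] > h / 2) li <- li - 1L
    ri <- p; while (ri < length(sm) && sm[ri] > h / 2) ri <- ri + 1L
    hwhm <- min(p - li, ri - p) * w
    max(hwhm / sqrt(2 * log(2)), w / 2)
  }, numeric(1))
  data.frame(center = x[peaks], sigma = sigma, amplitude = pmax(sm[peaks], 1))
}

#' Initial peak parameters at externally known centers
#'
#' When the number and approximate positions of populations are known from
#' the sample design (e.g. ladder lengths mapped through a calibration
#' curve), initialization does not need the histogram to be visibly
#' multimodal: each component starts at the supplied center with a width
#' proportional to it (constant-CV model) and an amplitude read off the
#' smoothed histogram.
#'
#' @param histogram an [make_histogram()] result.
#' @param centers numeric vector of expected component centers (same units
#'   as the histogram axis).
#' @param cv_guess initial relative width (sigma/center) of each component.
#' @return data.frame with columns `center`, `sigma`, `amplitude`.
#' @export
initial_peaks_at <- function(histogram, centers, cv_guess = 0.08) {
  stopifnot(inherits(histogram, "intensity_histogram"), length(centers) > 0)
  centers <- sort(centers)
  sm <- smooth_counts(histogram$counts, 5L)
  w <- mean(diff(histogram$bin_edges))
  idx <- pmin(pmax(findInterval(centers, histogram$bin_edges), 1L),
              length(sm))
  data.frame(center = centers,
             sigma = pmax(cv_guess * centers, w / 2),
             amplitude = pmax(sm[idx], 1))
}

#' Fit a sum of Gaussian functions to a histogram
#'
#' Nonlinear least squares (Levenberg-Marquardt, via
#' [minpack.lm::nls.lm()]) of \eqn{\sum_k A_k \exp(-(x - c_k)^2 / 2
#' \sigma_k^2)} to the bin counts (or bin masses, in mass mode), with
#' Poisson weighting \eqn{1/\sqrt{\max(y_i, 1)}} by default. Centers are
#' bounded to the data range and sigmas kept positive; no shared-width
#' constraint is imposed, since peak widths grow with fragment length.
#' Per-peak area is \eqn{A_k \sigma_k \sqrt{2\pi} / w} (molecules, or fg in
#' mass mode, for bin width \eqn{w}); center standard errors come from the
#' fit covariance.
#'
#' @param histogram an [make_histogram()] result.
#' @param init data.frame with `center`, `sigma`, `amplitude` (from
#'   [initial_peaks()] or [initial_peaks_at()]).
#' @param weighting `"poisson"` (default) or `"none"`.
#' @param max_fev maximum function evaluations.
#' @param ptol relative parameter convergence tolerance.
#' @return Object of class `mixture_fit`: list with `peaks` (data.frame
#'   `center`, `sigma`, `area`, `amplitude`, `center_se`, sorted by center),
#'   `residuals`, `fitted`, `r_squared`, `histogram`, `converged`, `info`.
#'   Non-convergence raises an error of class `smsizer_fit_error` carrying
#'   the best-so-far parameters in its `data` field.
#' @export
fit_gaussian_sum <- function(histogram, init, weighting = c("poisson", "none"),
                             max_fev = 10000L, ptol = 1e-8) {
  stopifnot(inherits(histogram, "intensity_histogram"))
  weighting <- match.arg(weighting)
  stopifnot(all(c("center", "sigma", "amplitude") %in% names(init)),
            nrow(init) >= 1, all(init$sigma > 0))
  x <- histogram$mids
  y <- histogram$counts
  k <- nrow(init)
  # Poisson-style weights 1/sqrt(y); the floor prevents empty bins from
  # getting infinite weight. Count histograms floor at one molecule; mass
  # histograms are on an arbitrary scale (fg), so the floor is tied to the
  # histogram maximum instead.
  floor_y <- if (isTRUE(histogram$weighted)) max(y) / 100 else 1
  wts <- if (weighting == "poisson") 1 / sqrt(pmax(y, floor_y))
  else rep(1, length(y))
  par <- c(rbind(init$amplitude, init$center, init$sigma))
  bw <- mean(diff(histogram$bin_edges))
  lower <- rep(c(0, min(histogram$bin_edges), bw / 10), k)
  upper <- rep(c(Inf, max(histogram$bin_edges), diff(range(x))), k)
  model <- function(p) {
    m <- 0
    for (j in seq_len(k)) {
      a <- p[3 * j - 2]; cc <- p[3 * j - 1]; s <- p[3 * j]
      m <- m + a * exp(-(x - cc)^2 / (2 * s^2))
    }
    m
  }
  resid_fn <- function(p) (model(p) - y) * wts
  fit <- minpack.lm::nls.lm(
    par = par, fn = resid_fn, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(
      maxfev = max_fev, maxiter = 1000L, ptol = ptol, ftol = ptol))
  if (!(fit$info %in% 1:4)) {
    stop(errorCondition(
      paste0("Gaussian-sum fit did not converge (nls.lm info ", fit$info,
             ": ", fit$message, ")"),
      class = c("smsizer_fit_error", "error"),
      data = list(par = fit$par, info = fit$info, deviance = fit$deviance)))
  }
  p <- fit$par
  se <- rep(NA_real_, length(p))
  dof <- length(y) - length(p)
  if (dof > 0) {
    cv <- tryCatch(chol2inv(chol(fit$hessian)) * fit$deviance / dof,
                   error = function(e) NULL)
    if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
    else warning("singular fit covariance; standard errors unavailable")
  }
  idx <- seq_len(k)
  peaks <- data.frame(
    amplitude = p[3 * idx - 2],
    center = p[3 * idx - 1],
    sigma = p[3 * idx],
    center_se = se[3 * idx - 1])
  peaks$area <- peaks$amplitude * peaks$sigma * sqrt(2 * pi) / bw
  ord <- order(peaks$center)
  peaks <- peaks[ord, c("center", "sigma", "area", "amplitude", "center_se")]
  rownames(peaks) <- NULL
  fitted <- model(p)
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(peaks = peaks,
         residuals = y - fitted,
         fitted = fitted,
         r_squared = if (ss_tot > 0) 1 - sum((y - fitted)^2) / ss_tot else NA,
         histogram = histogram,
         converged = TRUE,
         info = fit$info),
    class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: %d components, R^2 = %.5f\n",
              nrow(x$peaks), x$r_squared))
  print(format(x$peaks, digits = 5), ...)
  invisible(x)
}
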