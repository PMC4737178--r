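#' Estimate the translation between the two color channels
#'
#' Builds the 2-D histogram of pairwise offsets (cy5 - yoyo) between all spot
#' pairs within `max_shift` and returns the mode, refined by averaging the
#' offsets falling within 1 px of it. With fewer than 10 spots in either
#' channel (or no consistent offset) the estimate falls back to (0, 0) with a
#' warning.
#'
#' @param yoyo_spots,cy5_spots spot data.frames with columns `x`, `y`.
#' @param max_shift largest translation considered (pixels).
#' @param bin histogram bin width (pixels).
#' @return numeric c(dx, dy) such that `cy5 - shift` registers onto yoyo.
#' @export
estimate_channel_shift <- function(yoyo_spots, cy5_spots, max_shift = 10,
                                   bin = 0.5) {
  if (nrow(yoyo_spots) < 10 || nrow(cy5_spots) < 10) {
    warning("too few spots to estimate channel shift; assuming (0, 0)")
    return(c(dx = 0, dy = 0))
  }
  dx <- outer(cy5_spots$x, yoyo_spots$x, "-")
  dy <- outer(cy5_spots$y, yoyo_spots$y, "-")
  ok <- abs(dx) <= max_shift & abs(dy) <= max_shift
  if (!any(ok)) {
    warning("no spot pairs within max_shift; assuming (0, 0)")
    return(c(dx = 0, dy = 0))
  }
  dx <- dx[ok]; dy <- dy[ok]
  brks <- seq(-max_shift - bin, max_shift + bin, by = bin)
  ix <- findInterval(dx, brks); iy <- findInterval(dy, brks)
  tab <- table(ix, iy)
  top <- which(tab == max(tab), arr.ind = TRUE)[1, , drop = TRUE]
  mode_dx <- brks[as.integer(rownames(tab)[top[1]])] + bin / 2
  mode_dy <- brks[as.integer(colnames(tab)[top[2]])] + bin / 2
  near <- abs(dx - mode_dx) <= 1 & abs(dy - mode_dy) <= 1
  # require the mode to stand out from the random-pair background
  if (sum(near) < max(5, 0.05 * min(nrow(yoyo_spots), nrow(cy5_spots)))) {
    warning("no consistent channel offset found; assuming (0, 0)")
    return(c(dx = 0, dy = 0))
  }
  c(dx = mean(dx[near]), dy = mean(dy[near]))
}

#' Classify YOYO-1 spots as reference or sample by colocalization
#'
#' A YOYO-1 spot is classified `reference` when a Cy5 spot lies within
#' `radius` pixels of it (after removing the channel shift), `sample`
#' otherwise. Matching is one-to-one: candidate pairs are sorted by ascending
#' distance (ties broken lexicographically by spot order) and accepted
#' greedily, so each Cy5 spot is used at most once and the result is
#' symmetric in the two channels. Spots are matched within each FOV
#' independently.
#'
#' @param yoyo_spots,cy5_spots spot data.frames with columns `fov`, `x`, `y`
#'   (plus any measurement columns, carried through for the yoyo spots).
#' @param radius colocalization radius in pixels.
#' @param shift numeric c(dx, dy) from [estimate_channel_shift()].
#' @return `yoyo_spots` with added columns `class` ("reference"/"sample"),
#'   `matched_cy5` (row index into `cy5_spots` or NA) and `match_distance`
#'   (pixels or NA).
#' @export
colocalize <- function(yoyo_spots, cy5_spots, radius = 2, shift = c(0, 0)) {
  stopifnot(radius > 0)
  out <- yoyo_spots
  out$class <- rep("sample", nrow(out))
  out$matched_cy5 <- rep(NA_integer_, nrow(out))
  out$match_distance <- rep(NA_real_, nrow(out))
  if (nrow(yoyo_spots) == 0 || is.null(cy5_spots) || nrow(cy5_spots) == 0)
    return(out)
  yfov <- if ("fov" %in% names(yoyo_spots)) yoyo_spots$fov else rep(1L, nrow(yoyo_spots))
  cfov <- if ("fov" %in% names(cy5_spots)) cy5_spots$fov else rep(1L, nrow(cy5_spots))
  cx <- cy5_spots$x - shift[1]
  cy <- cy5_spots$y - shift[2]
  for (f in unique(yfov)) {
    yi <- which(yfov == f); ci <- which(cfov == f)
    if (length(ci) == 0) next
    d2 <- outer(yoyo_spots$x[yi], cx[ci], "-")^2 +
      outer(yoyo_spots$y[yi], cy[ci], "-")^2
    cand <- which(d2 <= radius^2, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    d <- sqrt(d2[cand])
    ord <- order(d, cand[, 1], cand[, 2])
    used_y <- logical(length(yi)); used_c <- logical(length(ci))
    for (k in ord) {
      a <- cand[k, 1]; b <- cand[k, 2]
      if (used_y[a] || used_c[b]) next
      used_y[a] <- TRUE; used_c[b] <- TRUE
      out$class[yi[a]] <- "reference"
      out$matched_cy5[yi[a]] <- ci[b]
      out$match_distance[yi[a]] <- d[k]
    }
  }
  out
}
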