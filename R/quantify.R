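# physical constants for DNA mass arithmetic
.N_A <- 6.02214076e23           # Avogadro, mol^-1
.M_BP_DEFAULT <- 650            # average dsDNA molar mass, g mol^-1 bp^-1

#' Mass of DNA in femtograms
#'
#' `mass_fg = length_bp * M_bp / N_A * 1e15`.
#'
#' @param length_bp fragment length(s), bp.
#' @param m_bp average base-pair molar mass, g/mol/bp.
#' @return fg per molecule.
#' @export
bp_to_fg <- function(length_bp, m_bp = .M_BP_DEFAULT) {
  length_bp * m_bp / .N_A * 1e15
}

#' Convert histogram counts into DNA amounts in femtograms
#'
#' Each bin's molecule count is multiplied by the mass of one molecule at
#' the bin-center length.
#'
#' @param bin_centers bin-center lengths, bp.
#' @param counts molecule counts per bin (non-negative).
#' @param m_bp average base-pair molar mass, g/mol/bp.
#' @return fg per bin.
#' @export
counts_to_mass <- function(bin_centers, counts, m_bp = .M_BP_DEFAULT) {
  if (any(counts < 0)) stop("counts must be non-negative")
  counts * bp_to_fg(bin_centers, m_bp)
}

#' Length and mass distribution of sized molecules
#'
#' Bins the molecule lengths and reports, per bin, the molecule count and
#' DNA mass in femtograms. By default each molecule contributes its exact
#' mass (`L * M_bp / N_A`) to its bin, which removes the bin-center
#' approximation error; `mode = "bin-center"` reproduces the coarser
#' count-times-bin-center conversion.
#'
#' @param lengths_bp molecule lengths in bp (`NA` dropped).
#' @param binning passed to [make_histogram()] (default 256 equal bins).
#' @param m_bp average base-pair molar mass, g/mol/bp.
#' @param mode `"exact"` or `"bin-center"`.
#' @return Object of class `size_distribution`: data.frame with `bin_bp`
#'   (centers), `count`, `mass_fg`, plus attributes `n_molecules`, `m_bp`.
#' @export
size_distribution <- function(lengths_bp, binning = 256L,
                              m_bp = .M_BP_DEFAULT,
                              mode = c("exact", "bin-center")) {
  mode <- match.arg(mode)
  lengths_bp <- lengths_bp[!is.na(lengths_bp)]
  if (length(lengths_bp) == 0) stop("no molecules to bin")
  ch <- make_histogram(lengths_bp, binning = binning)
  mass <- if (mode == "exact") {
    mh <- make_histogram(lengths_bp, weights = bp_to_fg(lengths_bp, m_bp),
                         binning = ch$bin_edges)
    mh$counts
  } else {
    counts_to_mass(ch$mids, ch$counts, m_bp)
  }
  out <- data.frame(bin_bp = ch$mids, count = ch$counts, mass_fg = mass)
  attr(out, "n_molecules") <- length(lengths_bp)
  attr(out, "m_bp") <- m_bp
  attr(out, "bin_edges") <- ch$bin_edges
  class(out) <- c("size_distribution", "data.frame")
  out
}

#' Total sampled DNA mass
#'
#' @param distribution a [size_distribution()] (or any data.frame with a
#'   `mass_fg` column).
#' @return Total femtograms.
#' @export
sampled_mass <- function(distribution) {
  if (is.null(distribution) || nrow(distribution) == 0) return(0)
  sum(distribution$mass_fg)
}

#' Per-population lengths and amounts from a mass-weighted mixture fit
#'
#' For a Gaussian-sum fit of the mass-vs-length histogram, each component's
#' center is the population length (bp), its area the population amount
#' (fg), and its normalized amount the area divided by the sum over all
#' detected populations.
#'
#' @param fit a [fit_gaussian_sum()] result on a mass-weighted length
#'   histogram.
#' @return data.frame with `length_bp`, `length_se`, `mass_fg`,
#'   `normalized_amount` (summing to 1).
#' @export
population_summary <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  pk <- fit$peaks
  if (nrow(pk) > 1) {
    overlap <- diff(pk$center) < (pk$sigma[-nrow(pk)] + pk$sigma[-1])
    if (any(overlap))
      warning(sum(overlap), " adjacent component pair(s) overlap within ",
              "one sigma; their areas may be poorly resolved")
  }
  data.frame(
    length_bp = pk$center,
    length_se = pk$center_se,
    mass_fg = pk$area,
    normalized_amount = pk$area / sum(pk$area))
}

#' Stability of the size distribution under subsampling
#'
#' Draws random subsets of the sized molecules, redoes the mass histogram
#' and Gaussian decomposition on each, and reports the per-fraction
#' population tables — emulating re-analysis of ever smaller sampled DNA
#' amounts. Populations whose fitted amount corresponds to fewer than
#' `min_molecules` molecules are flagged `unresolved`.
#'
#' @param lengths_bp sized molecule lengths (bp, `NA` dropped).
#' @param fractions subsample fractions in (0, 1].
#' @param seed RNG seed.
#' @param expected_lengths population centers used to initialize each refit
#'   (ladder design); `NULL` for automatic peak detection.
#' @param binning,m_bp as in [size_distribution()].
#' @param min_molecules resolution floor per population.
#' @return Named list (one element per fraction) with `fraction`,
#'   `sampled_fg`, `n_molecules` and `populations` (with `unresolved` flag).
#' @export
subsample_analysis <- function(lengths_bp, fractions, seed = 1L,
                               expected_lengths = NULL, binning = 256L,
                               m_bp = .M_BP_DEFAULT, min_molecules = 10L) {
  stopifnot(all(fractions > 0 & fractions <= 1))
  lengths_bp <- lengths_bp[!is.na(lengths_bp)]
  n <- length(lengths_bp)
  out <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    set.seed(seed + i)
    idx <- if (f >= 1) seq_len(n) else sample.int(n, floor(f * n))
    sub <- lengths_bp[idx]
    dist <- size_distribution(sub, binning = binning, m_bp = m_bp)
    hist <- structure(
      list(bin_edges = attr(dist, "bin_edges"),
           mids = dist$bin_bp, counts = dist$mass_fg,
           n_molecules = length(sub), weighted = TRUE),
      class = "intensity_histogram")
    init <- if (is.null(expected_lengths)) initial_peaks(hist)
    else initial_peaks_at(hist, expected_lengths)
    pops <- tryCatch({
      fit <- fit_gaussian_sum(hist, init)
      population_summary(fit)
    }, error = function(e) NULL)
    if (!is.null(pops)) {
      pops$unresolved <- pops$mass_fg / bp_to_fg(pops$length_bp, m_bp) <
        min_molecules
    }
    out[[as.character(f)]] <- list(
      fraction = f,
      sampled_fg = sampled_mass(dist),
      n_molecules = length(sub),
      populations = pops)
  }
  out
}
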