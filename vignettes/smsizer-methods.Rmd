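---
title: "Single-molecule DNA sizing: model, calibration and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule DNA sizing: model, calibration and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

A bis-intercalating dye such as YOYO-1 stains double-stranded DNA in
proportion to the number of intercalation sites, so the integrated
fluorescence of a single surface-deposited molecule is, to good
approximation, proportional to its length:

$$ I \;=\; g \cdot L \cdot q \cdot e^{\varepsilon},
   \qquad \varepsilon \sim N(0, \sigma^2), $$

with gain $g$ (au/bp), length $L$ (bp), quench factor $q \le 1$ (1 for
unlabeled molecules; below 1 for reference standards whose covalently
attached Cy5 labels quench YOYO-1 emission by energy transfer), and a
*multiplicative* lognormal noise term with relative scale
$\sigma$ (`intensity_cv`). Multiplicative noise is the physically sensible
choice for intercalation statistics — the absolute intensity spread of a
population grows with its length, which is exactly the monotonic broadening
of histogram peaks the assay shows — and it makes peak width
$\sigma_k \approx \sigma \cdot c_k$ for a population with intensity center
$c_k$.

The gain $g$ depends on staining conditions and acquisition parameters and
is *not* assumed known. Instead, two reference standards of known lengths
(2991 and 7029 bp here) are spiked into the sample before staining, so they
experience the same conditions; their fitted intensity peaks anchor an
in-situ linear calibration $L = a \cdot I + b$ that converts every sample
molecule's intensity to base pairs.

### Quenching and "imaged length"

A Cy5-labeled standard is dimmer than an unlabeled molecule of the same
length, so using its *true* length against its *quenched* intensity would
bias the calibration. The quench calibration (`quench_calibrate()`) fits the
intensity histograms of unlabeled PCR products of the standard lengths and
of the labeled standards, maps the labeled centers through the line defined
by the unlabeled centers and the true lengths, and so assigns each standard
an effective *imaged length* (the package ships the bench values
2721 ± 106 bp and 6456 ± 82 bp for the 2991 / 7029 bp standards in
`inst/extdata/quench_default.json`). Imaged lengths, not true lengths, enter
the per-run calibration. In fully synthetic runs the same calibration is
derived from a matched simulation (`simulate_quench_calibration()`), which
by default pools 10,000 molecules per standard — the equivalent of averaging
several calibration samples, as the bench workflow does.

### From lengths to amounts

Converted lengths are binned; each molecule contributes its exact mass
$L \cdot M_{bp} / N_A$ (with $M_{bp} = 650$ g/mol/bp by default,
configurable) to its bin, so total sampled mass is exact by construction and
reported in femtograms. The mass-vs-length histogram is decomposed into a
sum of Gaussians; each component's center is a population length, its area
the population amount in fg, and amounts are normalized to their sum for
the relative-abundance profile.

## Spot detection and photometry

Detection deliberately avoids PSF model fitting: at tens to hundreds of
thousands of molecules per sample, fixed-aperture photometry on a locally
background-subtracted image is fast, unbiased for isolated spots, and easy
to validate.

* **Local background** — a sliding windowed median (default 31 px, Rcpp
  implementation of Huang's constant-time histogram algorithm on a
  65536-level quantization of the image range; worst-case quantization error
  is range/131070, far below one gray level). The median is insensitive to
  diffraction-limited spots, so the map tracks the smooth background
  including vignetting.
* **Thresholding** — local maxima of the background-subtracted image above
  5 robust standard deviations (1.4826 × MAD); maxima closer than
  `min_separation` (5 px) merge into the brighter one.
* **Photometry** — circular aperture of radius 4 px (≈ 3 PSF sigmas at the
  default 1.3 px PSF, capturing ≈ 99% of the flux) summed over the
  background-subtracted image; centroids are intensity-weighted and
  sub-pixel.
* **Flat-field** — the smooth background is proportional to the illumination
  field, so a tensor-product quadratic surface fitted to the background map
  (that family contains separable vignetting domes exactly) estimates the
  relative illumination; measured intensities are divided by its normalized
  value at the spot. The correction is skipped when the fitted field is flat
  to within 5%. *Assumption:* frames are camera-bias-subtracted — an
  un-subtracted constant offset is indistinguishable from illumination shape
  in the background map and would flatten the estimated field. With
  flat-fielding disabled, detection output is exactly invariant to constant
  offsets.
* **Flags** — edge-touching, saturated, and oversized (footprint >
  `max_area_px`) spots are flagged and excluded from statistics, since
  clipped or blended intensities would bias sizing.

## Colocalization

Reference molecules are identified by spatial coincidence of a YOYO-1 and a
Cy5 spot. A translation offset between the channels is estimated first from
the mode of the pairwise-offset histogram (`estimate_channel_shift()`), then
spots are matched one-to-one: candidate pairs within the colocalization
radius (default 2 px, about one PSF width) are accepted greedily by
ascending distance, ties broken lexicographically. Greedy mutual matching is
deterministic, linear-time, symmetric under channel swap, and at realistic
densities (≤ 0.01 spots/px²) agrees with globally optimal assignment; the
false-colocalization rate for unrelated spots follows the Poisson law
$1 - e^{-\rho \pi r^2}$, which the test suite verifies by Monte Carlo.

## Histogram decomposition

Populations are recovered by nonlinear least squares of a Gaussian sum to
the binned data (Levenberg–Marquardt via `minpack.lm`), the estimator the
assay's figures imply (binned data + fitted sum + residual). Bins are
weighted by $1/\sqrt{\max(y_i, f)}$ (Poisson weighting; the floor $f$ is one
count for count histograms and 1% of the maximum for mass histograms, whose
scale is arbitrary). Centers are bounded to the data range, widths kept
positive, and no shared-width constraint is imposed — widths must be free to
grow with length. Convergence uses a relative parameter tolerance of 1e-8
and up to 10,000 function evaluations; the fit is deterministic (no random
restarts).

Initialization has two modes:

* **Automatic** (`initial_peaks()`): local maxima of a 5-bin moving-average
  smoothed histogram, de-duplicated within the smoothing window, kept when
  their topographic prominence exceeds 5 local Poisson noise units. The
  survivor count defines K. With `expected_k` given, the K *most prominent*
  maxima are used — ranking by raw height is unreliable because shoulder
  noise on a tall peak can outrank a genuinely smaller distant peak.
* **Design-informed** (`initial_peaks_at()`): when the population layout is
  known (a ladder of known lengths mapped through the calibration curve),
  components start at the expected centers with widths proportional to them.
  This is how the pipeline fits the 10-component sample decomposition, since
  K is known from the sample design.

Histogram binning for mixture analysis defaults to 256 equal-width bins in
the pipeline. The Freedman–Diaconis rule remains available in
`make_histogram()` but is a poor default for strongly multimodal intensity
data: it targets overall density estimation and yields bins wider than the
narrowest population peaks.

## What the simulator emulates — and what it does not

`simulate_molecules()` / `render_fov()` generate molecule tables and
two-channel 16-bit frames with: length-proportional lognormal intensities;
quenched reference standards visible in both channels; pixel-integrated
Gaussian PSF spots (default σ = 1.3 px) at uniform random positions with a
minimum-separation constraint (8 px, so detection tests are not confounded
by blending; an overlap switch exists for stress tests); a separable
quadratic illumination dome (minimum 0.7 of center); Poisson shot noise and
Gaussian read noise (σ = 3 au) on a 20 au background; and an optional
channel shift to exercise registration. Defaults give the faintest ladder
band (500 bp at gain 2 au/bp) a peak SNR well above the detection threshold.

Default `intensity_cv` is **0.06**. The value is the simulator's single most
consequential parameter: the number of modes of the 10-band ladder mixture
density is 10 for CV ≤ 0.07 but drops to 8 by CV 0.10, because the 8/10 kbp
(and 5/6 kbp) pairs merge into shoulders. Since the real assay resolves all
10 ladder peaks in its intensity histogram, its effective per-molecule CV
must be below ≈ 0.07, and 0.06 reproduces that qualitative structure with
margin. CV is exposed as a parameter, and the headline sizing benchmark is
deliberately run at the harsher CV = 0.10, where automatic mode counting is
impossible and only design-informed initialization can decompose the
histogram.

Not emulated: photobleaching/blinking kinetics, DNA stretching or combing
geometry, spot blending (by default), non-uniform surface deposition, and
chromatic PSF differences. Passing tests therefore demonstrate correctness
of the *analysis chain* under the assay's statistical model, not robustness
to every instrumental pathology of real microscopes.

## Numerical and design choices

* **Two-point calibration line carries a free intercept**: background and
  offset effects are real, and two points determine the line exactly. A
  through-origin option exists. Reference peaks are matched to imaged
  lengths by rank order of centers.
* **Reference-fit binning** adapts to the reference count (≈ 10 molecules
  per occupied bin, at most the configured bin count) so sparse reference
  sets still give smooth two-peak histograms.
* **Area identifiability**: partially overlapping components trade area with
  their neighbours (the fit covariance can be near-singular even when
  centers are stable); per-population amounts are reliable for isolated
  peaks while crowded neighbours are best read as pairwise sums. The
  overlap warning in `population_summary()` reports this.
* **Quantization and degenerate inputs**: histograms of constant data fall
  back to a unit-width bin; empty inputs error; non-positive converted
  lengths are flagged `NA` and excluded with a logged count.
* **Determinism**: every stochastic stage derives its seed from the run seed
  with fixed offsets (simulation +0, optics +1000, quench simulation +2000,
  subsampling +3000); a repeated run is artifact-identical.
* **Problem sizes**: benchmark runs use 2000 molecules per population
  (24,000 molecules, ~80 fields of view of 512×512 px), matching the
  "tens of thousands of molecules" regime of the assay while keeping a full
  two-channel run around a minute on one CPU.

## Known limitations

* The calibration is linear by construction; staining nonlinearity at very
  short fragments (< a few hundred bp) is outside the model.
* Flat-field correction assumes bias-subtracted frames (see above).
* Automatic K selection counts modes; populations merged beyond
  unimodality (CV ≳ 0.08 at this ladder spacing) require `expected_k` or
  design-informed initialization.
* Absolute concentration of the original solution is out of scope — only
  the sampled mass on the imaged surface is reported.

## A minimal end-to-end example

```{r, eval = FALSE}
library(smsizer)

cfg <- tempfile(fileext = ".yaml")
writeLines(c(
  "seed: 7",
  "out_dir: smsizer_demo",
  "simulate:",
  "  populations:",
  "    length_bp: [500, 1000, 1500, 2000, 3000, 4000, 5000, 6000, 8000, 10000]",
  "    count: [2000, 2000, 2000, 2000, 2000, 2000, 2000, 2000, 2000, 2000]",
  "  reference_populations:",
  "    length_bp: [2991, 7029]",
  "    count: [2000, 2000]",
  "    quench_factor: [0.910, 0.918]",
  "  intensity_cv: 0.10",
  "fit:",
  "  expected_lengths: [500, 1000, 1500, 2000, 3000, 4000, 5000, 6000, 8000, 10000]"
), cfg)
res <- run_assay(validate_config(cfg))
res$populations          # lengths (bp), amounts (fg), normalized amounts
res$summary$total_sampled_fg
```
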