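# smsizer

Sizing and mass quantification of DNA from single-molecule fluorescence
images.

## The problem

Gel- and capillary-electrophoresis instruments size DNA by partitioning a
population and reading an average profile; they need picogram-to-nanogram
inputs. When only femtograms of material are available — cell-free DNA,
micro-biopsies, sequencing-library QC — a different route is to *count
molecules*: stain the sample with an intercalating dye (YOYO-1), deposit it
on a coverslip, image individual molecules, and use the fact that
integrated fluorescence is proportional to fragment length,

&nbsp;&nbsp;&nbsp;&nbsp;*I = g · L · q · e^ε*,&nbsp;&nbsp; ε ~ N(0, σ²),

with unknown gain *g*, length *L* (bp), quench factor *q*, and
multiplicative noise of relative scale σ. Because *g* depends on staining
and acquisition conditions, the sample is spiked before staining with two
Cy5-labeled reference standards of known length (2991 and 7029 bp). After
two-channel imaging, reference molecules are recognized by colocalization
of their YOYO-1 and Cy5 spots; their fitted intensity peaks define an
in-situ linear calibration *L = a·I + b* that converts every sample
molecule's intensity to base pairs. Cy5 quenches YOYO-1 emission, so each
standard enters the calibration at its *imaged length* (its effective
apparent length, 2721 ± 106 and 6456 ± 82 bp for the shipped standards)
rather than its true length. Histogram counts are finally converted to DNA
amounts in femtograms via the molar mass of a base pair (650 g/mol/bp), and
the mass-vs-length histogram is decomposed into Gaussian components — one
per population, center = length, area = amount.

The package implements the full analysis chain:

| stage | functions |
|---|---|
| synthetic data (tables + rendered 16-bit two-channel TIFF FOVs) | `sim_config()`, `simulate_molecules()`, `render_fov()`, `simulate_dataset()` |
| spot detection & photometry (median background, aperture sums, flat-field) | `detection_params()`, `estimate_local_background()`, `detect_spots()`, `extract_intensities()` |
| reference classification by colocalization | `estimate_channel_shift()`, `colocalize()` |
| histogram decomposition (Gaussian sums, LM least squares) | `make_histogram()`, `initial_peaks()`, `initial_peaks_at()`, `fit_gaussian_sum()` |
| calibration (quench + two-/k-point line) | `quench_calibrate()`, `build_calibration()`, `intensity_to_length()` |
| quantification (fg masses, populations, subsampling) | `size_distribution()`, `counts_to_mass()`, `population_summary()`, `sampled_mass()`, `subsample_analysis()` |
| orchestration | `validate_config()`, `run_assay()`, `inst/cli/smsize` |

A synthetic-data module is first-class: every downstream stage is testable
against ground truth without microscope data.

## Worked example

A fully synthetic two-channel experiment: a 10-band 1 kb ladder
(500–10,000 bp, 2000 molecules per band, 10% intensity CV) spiked with the
two quenched reference standards, rendered into ~80 fields of view,
detected, classified, calibrated and quantified:

```r
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
res$curve
#> Calibration: length = 0.50524 bp/au * I + 22.305 bp (2 points)
res$populations
#>    length_bp length_se mass_fg normalized_amount
#> 1      511.4     5.419  1.0829          0.012365
#> 2     1008.1     9.594  2.0921          0.023889
#> 3     1500.0    23.607  3.1151          0.035570
#> 4     2003.7    27.160  4.3631          0.049819
#> 5     2935.2    27.487  4.4581          0.050904
#> ...
#> 10    9810.1    89.952 25.9520          0.296329
res$summary$total_sampled_fg
#> [1] 89.2
```

Population lengths land within a mean absolute error of **1.7%** of the
true band lengths; the run samples **89 fg** of DNA across ~20,000 sized
molecules. `run_assay()` leaves every intermediate artifact (spots,
classified molecules, reference peaks, calibration curve, distribution and
population tables, log, figures) in the output directory, and the same
stages are available as shell subcommands via `inst/cli/smsize`
(`simulate | detect | classify | fit | calibrate | quantify | run`).

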