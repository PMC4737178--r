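Package: smsizer
Title: Single-Molecule DNA Sizing from Two-Channel Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a single-molecule DNA sizing and mass quantification
    assay. Individual intercalator-stained DNA molecules deposited on a surface
    are detected as diffraction-limited spots in two-channel (YOYO-1 / Cy5)
    fluorescence images; spiked-in reference standards of known length are
    identified by colocalization between the channels, intensity histograms are
    decomposed into sums of Gaussian components, and an in-situ two-point (or
    k-point) calibration converts integrated spot intensities into DNA lengths
    in base pairs and per-population amounts in femtograms. A synthetic-data
    module simulates molecule tables and rendered fields of view with the same
    statistical structure (length-proportional intensity with multiplicative
    noise, Cy5 quenching of the reference standards, Gaussian point-spread
    spots on an unevenly illuminated background with shot and read noise), so
    the whole pipeline is testable end to end without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
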