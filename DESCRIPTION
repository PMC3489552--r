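Package: mrmassay
Title: Statistical Characterization of Stable-Isotope-Dilution MRM-MS Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Assay characterization for targeted quantitative proteomics by
    multiple reaction monitoring mass spectrometry with stable isotope
    dilution (SID-MRM-MS). Reads transition-level peak-area tables, computes
    peak-area ratios and measured concentrations, fits calibration curves by
    ordinary, weighted, robust (least-median-of-squares, least-trimmed-squares
    and MM-estimator) and log-space regression with bootstrap confidence
    intervals, estimates limits of detection and quantification by four
    methods (blank, blank plus low concentration, calibration curve, RSD
    limit), detects endogenous analyte by a robust-regression bootstrap test,
    flags imprecise and interference-affected transitions with the AuDIT
    relative-ratio algorithm, summarizes intra- and interlaboratory precision,
    and generates synthetic transition datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
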