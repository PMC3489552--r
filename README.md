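# mrmassay

Statistical characterization of stable-isotope-dilution MRM-MS assays.

Targeted proteomics quantifies peptides by multiple reaction monitoring
mass spectrometry (MRM-MS): a few precursor→fragment *transitions* are
monitored per peptide, with a stable isotope-labeled standard (SIS) spiked
into every sample at a known concentration. The peak area ratio
(PAR = analyte area / SIS area) converts to a measured concentration as
`measured = PAR × SIS concentration`, and a spike-in dilution series plus
blanks characterizes the assay. `mrmassay` is for the people who run and
evaluate such assays — method developers, core labs, multi-site studies —
and implements the characterization workflow end to end:

* **Calibration** — `fit_calibration()` fits
  `measured = slope × theoretical + intercept` by OLS, 1/x²-weighted LS,
  least-median-of-squares (LMS, breakdown point 0.5, exact pair search for
  n ≤ 50), least-trimmed-squares, the MM-estimator (bisquare, 95%
  efficiency), weighted MM, or log-space OLS; percentile-bootstrap or
  analytic confidence intervals (`bootstrap_ci()`), analytical sensitivity
  γ = slope/sd (`analytical_sensitivity()`). Standard model methods:
  `print`, `summary`, `coef`, `confint`, `predict`, `residuals`, `plot`.
* **Detection limits** — LOD/LOQ by four estimators: blank
  (`LOD = 3.29 σ_B`), blank + low concentration
  (`LOD = μ_B + t₁₋β(σ_B+σ_S)/√n`, the recommended default), calibration
  curve (`3 s_y|x / slope`), and RSD limit (fit
  `RSD = level · p₁^(1−p₂·log₁₀ level)`, solve for the target RSD);
  `LOQ = 3 × LOD` throughout.
* **Endogenous analyte** — `estimate_endogenous()` tests the LMS
  calibration intercept with a 99% percentile bootstrap;
  `endogenous_corrected_lod()` reports endogenous-free limits.
* **AuDIT** — `audit_transitions()` flags inaccurate/imprecise
  transitions from relative (branching) ratios: per-pair Welch t-tests of
  analyte vs SIS ratios, Benjamini–Hochberg correction, Brown–Kost
  combination of dependent p-values, and a PAR-CV filter; bad if combined
  p < 1e-5 or CV > 0.2. `evaluate_against_annotation()` and `audit_roc()`
  score the calls against expert annotation.
* **Precision** — `intra_lab_cv()`, `inter_lab_cv()` (median-of-site-CVs
  and pooled modes side by side) and `summarize_study()` build study-level
  tables with best-transition selection, slopes and percent recovery.
* **Synthetic data** — `generate_dataset(synth_config(...))` simulates the
  whole design (9-point 1–500 fmol/µL curve, blanks, 50 fmol/µL SIS spike,
  ≥3 transitions, constant-CV noise, noise floor, endogenous analyte,
  interference, saturation, multi-site biases) with ground-truth labels
  (`truth_labels()`), so everything above is testable offline.

## Worked example

Simulate a characterization experiment with 1 fmol/µL of endogenous
analyte and a co-eluting interference on the weakest transition, then
characterize it:

```r
library(mrmassay)

cfg <- synth_config(seed = 7, endogenous_conc = 1,
                    interference = list(transition_id = "PEP1.t3",
                                        magnitude = 8000))
ds <- generate_dataset(cfg)

fit <- fit_calibration(calibration_points(ds, "PEP1", "PEP1.t1"),
                       method = "wls")
summary(fit)
#> Calibration fit [wls]
#>   slope:           0.9877
#>   intercept:      1.137 fmol/uL
#>   residual scale:  0.09343
#>   R-squared:       0.9948
#>   n points:        36
#>   95% CI slope:     [0.9498, 1.026]  (analytic t)
#>   95% CI intercept: [1.037, 1.236]
#>   slope CI contains the ideal slope 1: yes
```

The slope is compatible with the ideal 1 and the intercept sits near the
injected endogenous 1 fmol/µL. The full per-transition table:

```r
set.seed(99)
characterize_transitions(ds, n_boot = 1000)
#>   transition_id slope  lod  loq endogenous_level lod_endogenous_free
#> 1       PEP1.t1 1.006 1.54 1.26             1.12               0.421
#> 2       PEP1.t2 0.954 2.11 2.46             1.29               0.820
#> 3       PEP1.t3 1.069 3.42 0.00            48.48               0.000
```

Transitions t1/t2 recover the endogenous level (~1.1–1.3 fmol/µL, LOD by
the default blank+low method, endogenous-corrected LOD alongside). On t3
the interference masquerades as an absurd 48 fmol/µL "endogenous level" —
exactly the failure mode AuDIT exists to catch:

```r
aud <- audit_transitions(ds)
head(subset(aud, flag == "bad")[, c("sample_id", "transition_id",
                                    "combined_p", "par_cv", "reason")])
#>    sample_id transition_id combined_p par_cv    reason
#> 2        C01       PEP1.t2   4.46e-07 0.2157 pvalue+cv
#> 6        C02       PEP1.t3   2.03e-08 0.0336    pvalue
#> 9        C03       PEP1.t3   2.11e-09 0.0232    pvalue
#> ...
```

The interfered transition is flagged across the curve (its branching
ratios disagree between analyte and SIS); its ratio partners pick up some
collateral flags, a documented property of the pairwise design. Dropping
t3 and re-quantifying on t1/t2 restores sane figures of merit.

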