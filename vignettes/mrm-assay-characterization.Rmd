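---
title: "Characterizing SID-MRM-MS assays with mrmassay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing SID-MRM-MS assays with mrmassay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmassay)
```

## The measurement model

Targeted quantification by multiple reaction monitoring mass spectrometry
(MRM-MS) monitors a small set of precursor-to-fragment *transitions* per
peptide, typically three or more. With stable isotope dilution (SID), a
stable isotope-labeled standard (SIS) peptide — chemically identical to the
analyte, shifted in mass — is spiked into every sample at a fixed, known
concentration (50 fmol/µL throughout the default design). The elementary
quantity is the **peak area ratio** (PAR): the analyte transition peak area
divided by the matched SIS transition peak area. Because analyte and SIS
co-elute and fragment identically, the PAR cancels most instrument-related
variation, and

> measured concentration = PAR × SIS spike concentration.

An assay characterization experiment spikes the analyte over a
concentration range (the default design uses nine levels, 1–500 fmol/µL,
four replicates each) plus repeated blanks (matrix + SIS, no analyte), and
fits the calibration line

> measured = slope × theoretical + intercept.

A slope of 1 and intercept of 0 is the ideal assay; a slope away from 1
indicates non-ideal recovery, and a genuinely positive intercept indicates
endogenous analyte already present in the matrix.

## Calibration regression (`fit_calibration()`)

Concentration measurements in MRM-MS are heteroscedastic — the variance
grows roughly with the square of the concentration (constant CV) — and the
upper and lower ends of the curve routinely leave the linear operating
region. `fit_calibration()` therefore offers, behind one interface:

* **`ols`** — ordinary least squares, the conventional baseline.
* **`wls`** — weighted least squares with weights $1/x^2$ on the
  theoretical concentration. The literature is ambiguous between weighting
  by inverse squared *measurement*, *level* or *variance*; this package
  weights by the inverse squared theoretical concentration, the common
  bioanalytical convention and the exact counterpart of constant-CV noise.
  Blanks ($x = 0$) are excluded automatically and the exclusion recorded.
* **`lms` / `lts`** — least median of squares and least trimmed squares
  (trim fraction 0.5). The LMS line minimizes the *median* squared
  residual and has a 0.5 breakdown point: up to half the points may sit
  outside the linear range without dragging the fit. The minimizer is
  found by searching candidate lines through point pairs — exhaustively
  over all $\binom{n}{2}$ pairs for $n \le 50$ (the estimator is then
  exactly the best pair-defined line, which unit tests verify against an
  independent brute-force search), or 3000 random pairs for larger $n$.
  Ties on the criterion break deterministically toward the slope closest
  to 1. LTS reuses the same search with the sum of the
  $\lfloor n/2\rfloor + 1$ smallest squared residuals.
* **`mm` / `wmm`** — the MM-estimator (via `MASS::rlm`): an S-estimator
  provides a high-breakdown initial scale, followed by an M-step with
  Tukey's bisquare tuned to 95% Gaussian efficiency ($c = 4.685$, at most
  100 iterations, tolerance $10^{-8}$). `wmm` multiplies in $1/x^2$ case
  weights. Because the S-step is resampling-based, MM results are
  reproducible only up to numerical tolerance (~$10^{-4}$ relative).
* **`log`** — OLS on $(\log_{10} x, \log_{10} y)$. The log transform
  homogenizes constant-CV variance, but its slope is **not** comparable to
  a linear-space slope: log-space slopes crowd toward 1 and flatter the
  assay (the acceptance checks demonstrate this on a slope-1.5 assay), and
  the intercept loses its endogenous-level interpretation. Results carry
  `method = "log"` and are never mixed into linear-space computations.

Confidence intervals are analytic t-intervals for the least-squares fits,
a normal approximation for MM, and a percentile bootstrap for LMS/LTS (or
for any method on request): resample points with replacement, refit, and
take the $\alpha$ and $1-\alpha$ percentiles with
$\alpha = (1-\text{conf})/2$. $R^2$ is reported as the squared correlation
of observed and fitted values, with the standing caveat that it says
nothing about the robustness or adequacy of a calibration fit. Analytical
sensitivity $\gamma = m/s$ (slope over measurement SD) is available as
`analytical_sensitivity()`.

## Limits of detection and quantification

Four estimators, all reported in measured-concentration units (fmol/µL),
all with LOQ = 3 × LOD unless noted:

* **Blank** (`lod_blank()`): LOD $= 3.29\,\sigma_B$ from at least three
  blank replicates, assuming Gaussian noise with 5% risks of false and
  missed detection. The classical LOQ is quoted both as 3 × LOD and as
  $10\sigma_B$; these differ slightly ($3 \times 3.29 = 9.87$), so the
  literal $10\sigma_B$ is available behind `loq_rule = "10sigma"` with
  3 × LOD the default.
* **Blank + low concentration** (`lod_blank_low()`), the package's
  recommended default: LOD
  $= \mu_B + t_{1-\beta,\,df}\,(\sigma_B + \sigma_S)/\sqrt{n}$, which
  acknowledges that the spread with analyte present at a low level
  ($\sigma_S$, from the lowest non-blank standard) can exceed the blank
  spread. Defaults: $\beta = 0.05$ and $df = n_B + n_S - 2$ (the source
  formulation states the risk but not the degrees of freedom; both are
  configurable).
* **Calibration curve** (`lod_calibration_curve()`): LOD
  $= 3\,s_{y|x}/\text{slope}$. Because $s_{y|x}$ absorbs residuals from
  the noisy top of the curve, this method is systematically conservative.
* **RSD limit** (`loq_rsd_limit()`): the observed relative standard
  deviation per level is modeled as
  $RSD = \text{level} \times p_1^{\,1 - p_2 \log_{10}(\text{level})}$
  ($\log$ read as $\log_{10}$, $p_1 > 0$ enforced by fitting
  $\log p_1$); the LOQ is the smallest in-range concentration where the
  fitted RSD reaches the target (default 20%), LOD = LOQ/3. The fit is
  least squares on the RSD scale, seeded by a closed-form log-linear
  start (the model is a pure power law in log-log coordinates) plus a
  small grid of fallback starts; the crossing is located by bisection,
  which tests verify against a dense grid. Blanks cannot enter (the model
  needs level > 0). If the fitted curve never crosses the target the LOQ
  is pinned to the nearest range endpoint and flagged `below_range` /
  `above_range`.

### Endogenous analyte

Endogenous analyte appears as a positive calibration intercept.
`estimate_endogenous()` fits the intercept by LMS — robust to the
off-linear portions of the curve, valid while at least half the points are
in the linear range — and bootstraps its percentile confidence interval
(default 99%, 1000+ resamples). If the lower limit is positive, the
endogenous level equals the intercept; otherwise it is reported as zero.
The endogenous-free LOD is then `max(LOD − level, 0)` with LOQ rescaled
(`endogenous_corrected_lod()`). A practical warning: LMS intercepts at
this design size ($\approx 40$ points) have a dispersion of a few tenths
of a fmol/µL at 10% measurement CV, so sub-0.3 fmol/µL endogenous calls
should be treated as tentative — mirrorred in the package's own
recovery simulations.

## AuDIT: inaccurate and imprecise transitions

Interference in one transition perturbs its *relative ratio* (branching
ratio) to the other transitions of the same precursor for the analyte but
not for the chemically identical SIS. `audit_transitions()` runs, per
(site, study, peptide, sample):

1. relative ratios per replicate, analyte and SIS, by either the
   **minimal-pairs** scheme (cyclic pairing over transitions sorted by id,
   so every transition enters exactly two ratios — the tie of "one other
   transition" is broken deterministically) or **all-pairs**;
2. a two-sided Welch t-test per pair, analyte vs SIS ratios across
   replicates (Welch because replicate counts are tiny and variances
   unequal; a log-ratio variant is available);
3. Benjamini–Hochberg correction across *all* ratio p-values of the run;
4. combination of each transition's dependent pair p-values by Fisher's
   statistic with the Brown–Kost moment correction, using the empirical
   correlation of the centered within-label log-ratio vectors (perfectly
   correlated duplicates collapse back to the single p-value; Šidák-min-p
   and Stouffer combiners are available since the combination method is a
   design choice rather than a uniquely defined step);
5. the CV of the PAR across replicates per transition and sample;
6. classification: **bad** if the corrected combined p-value falls below
   `1e-5` *or* the PAR CV exceeds `0.2`; both thresholds adjustable.

Evaluation against expert-style annotation builds the 2×2 contingency
table with a *positive* defined as a "good" call
(`evaluate_against_annotation()`, `contingency_metrics()`), reporting
accuracy, sensitivity and specificity as rounded percentages, plus an ROC
sweep of the p-value threshold at fixed CV threshold (`audit_roc()`).

Two behavioural notes, both visible in the synthetic experiments. First,
with four replicates a Welch test has at most six degrees of freedom, so
per-sample p-values below $10^{-5}$ require interference large relative to
noise (tens of noise SDs — i.e. a co-eluting signal of the same order as
the transition itself, which is exactly the situation the algorithm
targets); small distortions surface through the CV filter or at looser
thresholds instead. Second, in the minimal-pairs design a heavily
interfered transition can drag a neighbour past the threshold through
their shared ratio — a known property of pairwise designs; the all-pairs
scheme dilutes it as the transition count grows.

## Intra- and interlaboratory precision

CVs (sd/mean) are always computed on the original linear scale.
`intra_lab_cv()` gives the per-(site, level) CV of measured
concentrations; `inter_lab_cv()` reports, side by side, the **median of
site CVs** (a pure precision summary, blind to between-site bias) and the
**pooled CV** of all measurements at a level (the clinical convention,
which between-site mean shifts inflate — the two disagree exactly when
sites are individually tight but mutually shifted). `summarize_study()`
assembles the study table: per peptide and study phase it selects the
single best transition by lowest combined CV (median intra-lab CV across
sites and levels), then reports intra-lab CV medians and ranges, inter-lab
CVs, the calibration slope per site, and percent recovery. "Percent
recovery" has no canonical definition in this setting; the package reports
100 × median(measured/theoretical) over curve points, with the slope-based
variant (100 × slope) alongside, since the two are close but not equal.

## The synthetic-data generator

`generate_dataset(synth_config(...))` emulates the standard
characterization experiment so that every estimator above is testable with
known ground truth and no external data:

* nine-point curve 1–500 fmol/µL, 4 replicates, one blank sample measured
  4 times, 3 transitions with relative intensities 0.5/0.33/0.17, SIS at
  50 fmol/µL — the default study design;
* analyte area for transition $t$ at level $x$:
  $\text{base} \cdot f_t \cdot \text{bias}_{site} \cdot \text{slope}
  \cdot (x + e) \cdot e^{\varepsilon}$, SIS analogous at the spike
  concentration (no endogenous term and no site bias — the SIS is spiked
  after the lossy sample-preparation steps, which is also why
  multiplicative site biases on the analyte emulate between-lab recovery
  loss);
* multiplicative lognormal noise, split evenly between the two labels so
  that the replicate CV of the *measured concentration* equals `noise_cv`
  (default 5%, a well-performing assay; the variance then grows with
  concentration, reproducing the heteroscedasticity that motivates WLS);
* an additive Gaussian area floor (`blank_noise_sd`, default
  0.25 fmol/µL-equivalent on the strongest transition) applied to every
  analyte area — blanks see its absolute value, curve points are floored
  at zero. A shared noise floor is what gives blanks a non-zero spread
  and makes the RSD rise at the bottom of the curve, the premises of the
  blank-based and RSD-limit methods respectively;
* optional detector saturation (areas clip above a configured level,
  flattening the top of the curve for robust-regression tests), and
  optional interference: a constant area added to one analyte transition —
  by default in every curve sample, as a co-eluting contaminant would be —
  with `truth_labels()` emitting the matching good/bad annotation.

What the generator deliberately does **not** emulate: chromatographic
peak shapes and integration errors, retention-time drift, correlated
noise between transitions, non-Gaussian chemical noise at the analyte
m/z, and RSD structure beyond the single shared noise floor. Consequences
worth knowing: on synthetic data the RSD-limit and blank LOD methods
estimate essentially the same 3σ quantity and land on similar values,
whereas on real data the RSD-limit method is known to undershoot badly;
and passing synthetic tests demonstrates algorithmic correctness, not
performance on vendor exports.

## Numerical choices and test scale

Degenerate inputs are handled explicitly: two-point calibration fits
report residual scale 0 with a saturation note; ratio t-tests with both
sides constant return p = 1 (equal) or p = 0 (different, flagged
degenerate); zero SIS areas are errors at ratio time and report entries
at validation time; a zero mean PAR makes the CV undefined (error).
Bootstrap refits that fail are tolerated up to 10% of resamples.

The package's own simulations (unit tests and the acceptance script) use
100-seed batches for parameter-recovery and detection rates, 50-seed
batches for method-ordering tendencies, and 300-resample bootstraps
inside simulations (1000+ remains the recommendation for single
analyses) — sizes chosen to keep the full suite within a few minutes
while leaving the binomial noise on any reported rate below ~5 points.
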