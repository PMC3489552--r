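# Shared fixtures and independent oracles for the test suite.

# Exact-line calibration points.
line_points <- function(x = c(0, 1, 2, 5, 10, 20, 50), slope = 1,
                        intercept = 0) {
  data.frame(theoretical_conc = x, measured_conc = slope * x + intercept)
}

# Vector with exactly the requested mean and sample sd (length >= 2).
vec_with_moments <- function(n, mean, sd) {
  v <- seq_len(n)
  mean + sd * (v - base::mean(v)) / stats::sd(v)
}

# Independent brute-force least-median-of-squares oracle: plain R loop over
# all point-pair candidate lines, minimizing median squared residual.
oracle_lms <- function(x, y) {
  n <- length(x)
  best <- Inf
  bs <- NA_real_
  bi <- NA_real_
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (x[i] == x[j]) next
      sl <- (y[j] - y[i]) / (x[j] - x[i])
      ic <- y[i] - sl * x[i]
      cr <- stats::median((y - ic - sl * x)^2)
      if (cr < best) {
        best <- cr
        bs <- sl
        bi <- ic
      }
    }
  }
  list(slope = bs, intercept = bi, criterion = best)
}

# Hand-computed Welch two-sample t-test p-value.
oracle_welch_p <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  tt <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(-abs(tt), df)
}

# Minimal hand-built transition dataset: one peptide, one transition,
# analyte+SIS, with specified measured concentrations realized through
# peak areas at a 50 fmol/uL SIS spike.
dataset_from_measured <- function(theoretical, measured, sis_conc = 50,
                                  transition = "t1", peptide = "PEP",
                                  site = "site1", sis_area = 1000) {
  n <- length(theoretical)
  stopifnot(length(measured) == n)
  base <- data.frame(
    site_id = site, peptide_id = peptide, transition_id = transition,
    sample_id = sprintf("S%02d", seq_len(n)),
    sample_role = ifelse(theoretical == 0, "blank", "curve_point"),
    theoretical_conc = theoretical, replicate = 1L,
    stringsAsFactors = FALSE)
  rec <- rbind(
    cbind(base, label = "analyte",
          peak_area = measured / sis_conc * sis_area),
    cbind(base, label = "SIS", peak_area = sis_area))
  transition_dataset(rec, sis_conc = sis_conc)
}
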