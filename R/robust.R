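# Least-median-of-squares / least-trimmed-squares pair search.
#
# Candidate lines are defined by point pairs. For n <= 50 the search is
# exhaustive over all C(n, 2) pairs, which makes the minimizer exact over the
# pair-defined candidate set; above 50 points, 3000 random pairs are drawn
# from the current RNG stream. Ties on the criterion break toward the slope
# closest to 1 (the ideal calibration slope), which makes the result
# deterministic.

.LMS_MAX_EXHAUSTIVE <- 50L
.LMS_RANDOM_PAIRS <- 3000L

.fit_pair_search <- function(x, y, variant = c("lms", "lts")) {
  variant <- match.arg(variant)
  n <- length(x)
  if (n < 4L) stop("robust pair-search regression needs at least 4 points")
  if (length(unique(x)) < 2L) {
    stop("degenerate design: all theoretical concentrations identical")
  }

  if (n <= .LMS_MAX_EXHAUSTIVE) {
    pr <- utils::combn(n, 2L)
    i1 <- pr[1L, ]; i2 <- pr[2L, ]
  } else {
    i1 <- sample.int(n, .LMS_RANDOM_PAIRS, replace = TRUE)
    i2 <- sample.int(n - 1L, .LMS_RANDOM_PAIRS, replace = TRUE)
    i2 <- ifelse(i2 >= i1, i2 + 1L, i2)  # distinct indices
  }

  h <- floor(n / 2) + 1L  # trimmed count for LTS, trim fraction 0.5
  res <- pair_search_fit(as.numeric(x), as.numeric(y),
                         as.integer(i1), as.integer(i2), variant, h)
  if (res$n_candidates == 0L || !is.finite(res$criterion)) {
    stop("no valid candidate lines (all point pairs share one x)")
  }
  slope <- res$slope
  icpt <- res$intercept
  r <- y - icpt - slope * x
  med_r2 <- stats::median(r^2)
  # 1.4826 makes sqrt(median r^2) consistent for the Gaussian sd
  scale <- 1.4826 * sqrt(med_r2)
  list(slope = slope, intercept = icpt, residual_scale = scale,
       r_squared = .r2(y, icpt + slope * x),
       fitted = icpt + slope * x, residuals = r, n = n, converged = TRUE,
       criterion = res$criterion,
       exhaustive = n <= .LMS_MAX_EXHAUSTIVE)
}
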