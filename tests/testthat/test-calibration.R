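# Calibration regression strategies.

test_that("every fitter recovers an exact line, and log space is exact on power laws", {
  pts <- line_points(x = c(1, 2, 5, 10, 20, 50), slope = 2, intercept = 1)
  for (m in c("ols", "wls", "lms", "lts", "mm", "wmm")) {
    f <- fit_calibration(pts, m, ci = "none")
    expect_equal(f$slope, 2, tolerance = 1e-8, label = paste(m, "slope"))
    expect_equal(f$intercept, 1, tolerance = 1e-6,
                 label = paste(m, "intercept"))
    expect_equal(f$residual_scale, 0, tolerance = 1e-6)
    expect_equal(f$r_squared, 1, tolerance = 1e-8)
  }
  # the ideal assay: slope 1, intercept 0
  ideal <- fit_calibration(line_points(x = c(0, 1, 5, 10)), "ols",
                           ci = "none")
  expect_equal(ideal$slope, 1, tolerance = 1e-12)
  expect_equal(ideal$intercept, 0, tolerance = 1e-12)

  lg <- fit_calibration(line_points(x = c(1, 10, 100)), "log", ci = "none")
  expect_equal(lg$slope, 1, tolerance = 1e-12)
  expect_equal(lg$intercept, 0, tolerance = 1e-12)
  # y = x^2 is a log-space line with slope 2
  sq <- fit_calibration(
    data.frame(theoretical_conc = c(1, 10, 100),
               measured_conc = c(1, 100, 10000)), "log", ci = "none")
  expect_equal(sq$slope, 2, tolerance = 1e-12)
  expect_equal(sq$intercept, 0, tolerance = 1e-10)
})

test_that("saturated two-point fit interpolates with zero residual scale", {
  f <- fit_calibration(
    data.frame(theoretical_conc = c(1, 2), measured_conc = c(3, 5)),
    "ols", ci = "none")
  expect_equal(unname(coef(f)), c(1, 2))
  expect_equal(f$residual_scale, 0)
  expect_match(paste(f$notes, collapse = " "), "saturated")
})

test_that("blanks are excluded from weighted and log fits; degenerate designs error", {
  pts <- line_points(x = c(0, 0, 1, 2, 5, 10), slope = 1.5)
  f <- fit_calibration(pts, "wls", ci = "none")
  expect_equal(f$n_blanks_excluded, 2L)
  expect_equal(f$n_points, 4L)
  expect_equal(f$slope, 1.5, tolerance = 1e-10)
  expect_error(
    fit_calibration(line_points(x = rep(5, 6)), "ols", ci = "none"),
    "degenerate")
})

test_that("fitters are invariant to point order and equivariant under y-scaling", {
  set.seed(42)
  x <- rep(c(1, 2, 5, 10, 20, 50, 100, 200, 500), each = 2)
  y <- x * exp(rnorm(length(x), 0, 0.1))
  pts <- data.frame(theoretical_conc = x, measured_conc = y)
  shuf <- pts[sample(nrow(pts)), ]
  for (m in c("ols", "wls", "lms", "mm")) {
    f1 <- fit_calibration(pts, m, ci = "none")
    f2 <- fit_calibration(shuf, m, ci = "none")
    # the MM S-step initializer is resampling-based, so its order
    # invariance is numerical rather than exact
    tol <- if (m == "mm") 1e-3 else 1e-9
    expect_equal(coef(f1), coef(f2), tolerance = tol,
                 label = paste(m, "order invariance"))
    for (k in c(0.1, 7)) {
      sc <- pts
      sc$measured_conc <- k * sc$measured_conc
      fk <- fit_calibration(sc, m, ci = "none")
      expect_equal(fk$slope, k * f1$slope, tolerance = tol)
      expect_equal(fk$intercept, k * f1$intercept,
                   tolerance = max(tol, 1e-7))
      expect_equal(fk$residual_scale, k * f1$residual_scale,
                   tolerance = max(tol, 1e-7))
    }
  }
})

test_that("LMS matches the brute-force pair-search oracle and resists outliers", {
  # outlier recovery: 8 points on y = x, 3 gross high-end outliers
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  y <- x
  y[6:8] <- 10 * x[6:8]
  f <- fit_calibration(data.frame(theoretical_conc = x, measured_conc = y),
                       "lms", ci = "none")
  expect_equal(f$slope, 1, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)

  # the OLS slope is dragged much further by the outliers than LMS
  fo <- fit_calibration(data.frame(theoretical_conc = x, measured_conc = y),
                        "ols", ci = "none")
  expect_gt(abs(fo$slope - 1), 10 * abs(f$slope - 1))

  # oracle equality (attained criterion) over random fixtures, n <= 20
  set.seed(7)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    xx <- runif(n, 1, 100)
    yy <- xx + rnorm(n, 0, 3)
    out <- sample(n, floor(n / 3))
    yy[out] <- yy[out] * runif(length(out), 2, 8)
    fit <- fit_calibration(
      data.frame(theoretical_conc = xx, measured_conc = yy), "lms",
      ci = "none")
    orc <- oracle_lms(xx, yy)
    got <- median((yy - fit$intercept - fit$slope * xx)^2)
    expect_equal(got, orc$criterion, tolerance = 1e-9)
  }
})

test_that("LMS breakdown: a contaminant majority captures the fit", {
  # 5 of 9 points on y = 5x + 20, 4 on y = x
  x <- 1:9
  y <- x
  maj <- c(1, 3, 5, 7, 9)
  y[maj] <- 5 * x[maj] + 20
  f <- fit_calibration(data.frame(theoretical_conc = x, measured_conc = y),
                       "lms", ci = "none")
  expect_equal(f$slope, 5, tolerance = 1e-12)
  expect_equal(f$intercept, 20, tolerance = 1e-12)
})

test_that("MM-estimator resists high-end outliers and tracks WLS on skewed curves", {
  # saturation-style fixture: top of the curve flattens
  set.seed(21)
  x <- rep(c(1, 2, 5, 10, 20, 50, 100, 200, 500), each = 4)
  y <- pmin(x, 120) * exp(rnorm(length(x), 0, 0.08))
  pts <- data.frame(theoretical_conc = x, measured_conc = y)
  ols <- fit_calibration(pts, "ols", ci = "none")$slope
  wls <- fit_calibration(pts, "wls", ci = "none")$slope
  mm <- fit_calibration(pts, "mm", ci = "none")$slope
  expect_lt(abs(mm - wls), abs(ols - wls))

  # 20% gross outliers: MM median slope error does not exceed OLS's
  errs <- t(sapply(1:100, function(s) {
    set.seed(1000 + s)
    xx <- rep(c(1, 2, 5, 10, 20, 50, 100, 200, 500), each = 2)
    yy <- xx * exp(rnorm(length(xx), 0, 0.05))
    bad <- sample(length(xx), round(0.2 * length(xx)))
    yy[bad] <- yy[bad] * 5
    p <- data.frame(theoretical_conc = xx, measured_conc = yy)
    c(mm = abs(fit_calibration(p, "mm", ci = "none")$slope - 1),
      ols = abs(fit_calibration(p, "ols", ci = "none")$slope - 1))
  }))
  expect_lte(median(errs[, "mm"]), median(errs[, "ols"]))
})

test_that("WLS is more accurate than OLS under constant-CV noise (median error)", {
  errs <- t(sapply(1:50, function(s) {
    ds <- generate_dataset(synth_config(seed = s, noise_cv = 0.1,
                                        blank_noise_sd = 0))
    pts <- calibration_points(ds, "PEP1", "PEP1.t1")
    c(wls = abs(fit_calibration(pts, "wls", ci = "none")$slope - 1),
      ols = abs(fit_calibration(pts, "ols", ci = "none")$slope - 1))
  }))
  expect_lt(median(errs[, "wls"]), median(errs[, "ols"]))
})

test_that("all fitters converge to the generating slope on clean Gaussian data", {
  set.seed(31)
  x <- rep(c(1, 2, 5, 10, 20, 50, 100, 200, 500, 1000), each = 20)
  y <- 1.3 * x + 2 + rnorm(length(x), 0, 2)
  pts <- data.frame(theoretical_conc = x, measured_conc = y)
  for (m in c("ols", "wls", "lms", "mm")) {
    f <- fit_calibration(pts, m, ci = "none")
    expect_equal(f$slope, 1.3, tolerance = 0.05, label = paste(m, "n=200"))
  }
})

test_that("bootstrap interval mechanics: degeneracy, alpha mapping, guard rails", {
  pts <- line_points(x = c(1, 2, 5, 10, 20, 50), slope = 2, intercept = 1)
  set.seed(2)
  bs <- suppressWarnings(bootstrap_ci(pts, "ols", n_boot = 200,
                                      conf_level = 0.99))
  expect_equal(bs$slope_ci, c(2, 2), tolerance = 1e-12)
  expect_equal(bs$intercept_ci, c(1, 1), tolerance = 1e-12)
  expect_equal(bs$alpha, 0.005)
  expect_error(bootstrap_ci(pts, "ols", n_boot = 50), "at least 100")
  expect_warning(bootstrap_ci(pts, "ols", n_boot = 200), "below 1000")
})

test_that("bootstrap slope interval covers the generating slope", {
  hits <- sapply(1:30, function(s) {
    ds <- generate_dataset(synth_config(seed = 400 + s, noise_cv = 0.1,
                                        blank_noise_sd = 0))
    pts <- calibration_points(ds, "PEP1", "PEP1.t1")
    bs <- suppressWarnings(bootstrap_ci(pts, "ols", n_boot = 400,
                                        conf_level = 0.99))
    bs$slope_ci[1] <= 1 && 1 <= bs$slope_ci[2]
  })
  expect_gte(mean(hits), 0.9)
})

test_that("analytical sensitivity is slope over measurement sd", {
  expect_equal(analytical_sensitivity(2, 0.5), 4)
  expect_equal(analytical_sensitivity(1, 1), 1)
  expect_equal(analytical_sensitivity(2 * 1.7, 0.3),
               2 * analytical_sensitivity(1.7, 0.3))
  expect_error(analytical_sensitivity(1, 0), "positive")
})
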