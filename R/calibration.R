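# Calibration-curve regression: measured vs theoretical concentration.
#
# The regression model is
#   measured concentration = slope * theoretical concentration + intercept
# An ideal assay has slope 1 and intercept 0; a positive intercept signals
# endogenous analyte and a slope away from 1 signals non-ideal recovery.

.CAL_METHODS <- c("ols", "wls", "lms", "lts", "mm", "wmm", "log")

#' Fit a calibration curve
#'
#' Fits `measured_conc ~ theoretical_conc` by one of seven strategies:
#'
#' * `"ols"` — ordinary least squares.
#' * `"wls"` — weighted least squares with inverse-squared-concentration
#'   weights (`1/x^2`), the standard bioanalytical weighting for
#'   constant-CV (heteroscedastic) noise.
#' * `"lms"` — least median of squares: the line minimizing the median of
#'   squared residuals, found by exhaustive search over all point-pair
#'   candidate lines for n <= 50 (random pairs above); breakdown point 0.5.
#' * `"lts"` — least trimmed squares (trim fraction 0.5), same search
#'   machinery as `"lms"`.
#' * `"mm"` — MM-estimator: S-estimator initial scale followed by an M-step
#'   with Tukey bisquare psi tuned to 95% Gaussian efficiency (c = 4.685).
#' * `"wmm"` — MM-estimator with `1/x^2` case weights.
#' * `"log"` — OLS on `(log10 x, log10 y)`; slope and intercept are reported
#'   in log space and are *not* interchangeable with linear-space
#'   parameters.
#'
#' Blanks (`theoretical_conc == 0`) are excluded automatically from the
#' weighted and log-space fits (the weights/logs are undefined there) and
#' included everywhere else; the number excluded is recorded on the fit.
#'
#' @param points data frame with columns `theoretical_conc` and
#'   `measured_conc` (fmol/uL), e.g. from [calibration_points()].
#' @param method fitting strategy, see above.
#' @param ci `"auto"` (analytic t-intervals for least-squares fits, normal
#'   approximation for MM, percentile bootstrap for LMS/LTS), `"boot"`
#'   (percentile bootstrap for any method) or `"none"`.
#' @param conf_level confidence level for slope/intercept intervals.
#' @param n_boot bootstrap resamples when `ci = "boot"` (or `"auto"` for
#'   LMS/LTS).
#' @return Object of class `calibration_fit` with components `slope`,
#'   `intercept`, `residual_scale` (`s_y|x`, fmol/uL; robust scale
#'   `1.4826 * sqrt(median r^2)` for LMS/LTS, M-scale for MM), `r_squared`,
#'   `slope_ci`, `intercept_ci`, `n_points`, `weighting` and the data used.
#'   `r_squared` is the squared correlation between observed and fitted
#'   values; note that it does not measure the robustness or adequacy of the
#'   fit.  Methods: [print()], [summary()], [coef()], [predict()],
#'   [residuals()], [fitted()], [confint()], [plot()].
#' @export
fit_calibration <- function(points,
                            method = c("ols", "wls", "lms", "lts", "mm",
                                       "wmm", "log"),
                            ci = c("auto", "boot", "none"),
                            conf_level = 0.95, n_boot = 1000) {
  method <- match.arg(method)
  ci <- match.arg(ci)
  xy <- .as_xy(points)
  notes <- character()

  n_blanks_excluded <- 0L
  if (method %in% c("wls", "wmm", "log")) {
    blank <- xy$x == 0
    n_blanks_excluded <- sum(blank)
    if (n_blanks_excluded > 0L) {
      xy <- xy[!blank, , drop = FALSE]
      notes <- c(notes, sprintf(
        "%d blank point(s) (theoretical_conc = 0) excluded from the '%s' fit",
        n_blanks_excluded, method))
    }
  }

  core <- .fit_core(xy$x, xy$y, method)
  notes <- c(notes, core$notes)

  slope_ci <- c(NA_real_, NA_real_)
  intercept_ci <- c(NA_real_, NA_real_)
  ci_method <- "none"
  if (ci == "boot" || (ci == "auto" && method %in% c("lms", "lts"))) {
    bs <- bootstrap_ci(xy, method = method, n_boot = n_boot,
                       conf_level = conf_level)
    slope_ci <- bs$slope_ci
    intercept_ci <- bs$intercept_ci
    ci_method <- "percentile bootstrap"
  } else if (ci == "auto" && method %in% c("ols", "wls", "log")) {
    if (core$n > 2L) {
      cis <- stats::confint(core$lm_fit, level = conf_level)
      intercept_ci <- unname(cis[1L, ])
      slope_ci <- unname(cis[2L, ])
      ci_method <- "analytic t"
    }
  } else if (ci == "auto" && method %in% c("mm", "wmm")) {
    se <- core$se
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    slope_ci <- core$slope + c(-1, 1) * z * se["slope"]
    intercept_ci <- core$intercept + c(-1, 1) * z * se["intercept"]
    ci_method <- "normal approximation"
  }

  structure(list(method = method,
                 weighting = if (method %in% c("wls", "wmm"))
                   "inv_x_squared" else "none",
                 slope = core$slope, intercept = core$intercept,
                 residual_scale = core$residual_scale,
                 r_squared = core$r_squared,
                 slope_ci = unname(slope_ci),
                 intercept_ci = unname(intercept_ci),
                 conf_level = conf_level, ci_method = ci_method,
                 n_points = core$n,
                 n_blanks_excluded = n_blanks_excluded,
                 data = xy, fitted = core$fitted,
                 residuals = core$residuals,
                 converged = core$converged, notes = notes,
                 call = match.call()),
            class = "calibration_fit")
}

# Accepts calibration-point data frames (or anything with x/y columns) and
# returns a canonical two-column frame.
.as_xy <- function(points) {
  if (is.data.frame(points)) {
    if (all(c("theoretical_conc", "measured_conc") %in% names(points))) {
      xy <- data.frame(x = points$theoretical_conc, y = points$measured_conc)
    } else if (all(c("x", "y") %in% names(points))) {
      xy <- data.frame(x = points$x, y = points$y)
    } else {
      stop("'points' must have columns theoretical_conc/measured_conc")
    }
  } else {
    stop("'points' must be a data frame of calibration points")
  }
  xy <- xy[stats::complete.cases(xy), , drop = FALSE]
  rownames(xy) <- NULL
  xy
}

# Shared fitting core used by fit_calibration() and the bootstrap; operates
# on bare vectors for speed.
.fit_core <- function(x, y, method) {
  n <- length(x)
  notes <- character()
  switch(method,
    ols = , wls = {
      if (n < 2L) stop("need at least 2 points")
      if (length(unique(x)) < 2L) {
        stop("degenerate design: all theoretical concentrations identical")
      }
      if (n < 3L && method == "ols") {
        notes <- c(notes, "saturated fit: 2 points, residual scale reported as 0")
      }
      w <- if (method == "wls") 1 / x^2 else rep(1, n)
      if (method == "wls" && any(x == 0)) {
        stop("inverse-squared-concentration weighting requires all ",
             "theoretical_conc > 0; exclude blanks first")
      }
      fit <- stats::lm(y ~ x, weights = if (method == "wls") w else NULL)
      res <- unname(stats::residuals(fit))
      sigma <- if (n > 2L) sqrt(sum(w * res^2) / (n - 2L)) else 0
      if (n == 2L) notes <- c(notes, "saturated fit: residual scale undefined, reported as 0")
      list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
           residual_scale = sigma, r_squared = .r2(y, fitted(fit)),
           fitted = unname(fitted(fit)), residuals = res, n = n,
           converged = TRUE, lm_fit = fit, notes = notes)
    },
    log = {
      if (any(x <= 0) || any(y <= 0)) {
        stop("log-space fit requires positive concentrations; ",
             "exclude blanks and zero measurements")
      }
      if (n < 3L) stop("need at least 3 points for the log-space fit")
      lx <- log10(x); ly <- log10(y)
      fit <- stats::lm(ly ~ lx)
      res <- unname(stats::residuals(fit))
      list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
           residual_scale = if (n > 2L) sqrt(sum(res^2) / (n - 2L)) else 0,
           r_squared = .r2(ly, fitted(fit)),
           fitted = unname(fitted(fit)), residuals = res, n = n,
           converged = TRUE, lm_fit = fit, notes = notes)
    },
    lms = , lts = {
      core <- .fit_pair_search(x, y, variant = method)
      core$notes <- notes
      core
    },
    mm = , wmm = {
      core <- .fit_mm(x, y,
                      weights = if (method == "wmm") 1 / x^2 else NULL)
      core$notes <- notes
      core
    },
    stop("unknown method: ", method))
}

# Squared correlation between observed and fitted values; equals classical
# R^2 for least squares with intercept, stays within [0,1] for robust fits.
.r2 <- function(y, fitted) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(if (all(abs(y - fitted) < 1e-12)) 1 else 0)
  if (stats::var(fitted) == 0) return(0)
  min(1, max(0, stats::cor(y, fitted)^2))
}

.fit_mm <- function(x, y, weights = NULL, maxit = 100L, acc = 1e-8) {
  n <- length(x)
  if (n < 4L) stop("MM-estimator needs at least 4 points")
  if (!is.null(weights) && any(x <= 0)) {
    stop("weighted MM requires all theoretical_conc > 0; exclude blanks first")
  }
  # degenerate-scale guard: data exactly on a line (zero residual scale
  # breaks the S/M iterations) -> return the interpolating LS line
  cf0 <- stats::.lm.fit(cbind(1, x), y)$coefficients
  r0 <- y - cf0[1L] - cf0[2L] * x
  if (max(abs(r0)) <= 1e-10 * (1 + max(abs(y)))) {
    return(list(slope = unname(cf0[2L]), intercept = unname(cf0[1L]),
                residual_scale = 0, r_squared = 1,
                fitted = y - r0, residuals = r0, n = n, converged = TRUE,
                se = c(intercept = 0, slope = 0)))
  }
  dat <- data.frame(x = x, y = y)
  fit <- if (is.null(weights)) {
    MASS::rlm(y ~ x, data = dat, method = "MM", psi = MASS::psi.bisquare,
              c = 4.685, maxit = maxit, acc = acc)
  } else {
    MASS::rlm(y ~ x, data = dat, weights = weights, method = "MM",
              psi = MASS::psi.bisquare, c = 4.685, maxit = maxit, acc = acc,
              wt.method = "case")
  }
  if (!fit$converged) {
    stop("MM-estimator failed to converge in ", maxit,
         " iterations (final scale ", signif(fit$s, 4), ")")
  }
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       residual_scale = unname(fit$s), r_squared = .r2(y, fitted(fit)),
       fitted = unname(fitted(fit)), residuals = unname(residuals(fit)),
       n = n, converged = TRUE,
       se = c(intercept = sm$coefficients[1L, 2L],
              slope = sm$coefficients[2L, 2L]))
}

#' Analytical sensitivity of a calibration curve
#'
#' The analytical sensitivity `gamma = m / s` relates the calibration slope
#' `m` to the standard deviation `s` of the measurement, so that assays are
#' compared on their ability to resolve small concentration differences
#' rather than on slope alone.
#'
#' @param slope calibration-curve slope.
#' @param measurement_sd positive standard deviation of the measurement, in
#'   the units of the measured concentration.
#' @return `slope / measurement_sd`.
#' @export
analytical_sensitivity <- function(slope, measurement_sd) {
  if (!is.numeric(measurement_sd) || any(is.na(measurement_sd)) ||
      any(measurement_sd <= 0)) {
    stop("'measurement_sd' must be positive")
  }
  slope / measurement_sd
}

#' Bootstrap confidence intervals for calibration parameters
#'
#' Resamples calibration points with replacement, refits with the requested
#' strategy, and returns percentile intervals for the slope and intercept at
#' levels `alpha` and `1 - alpha` with `alpha = (1 - conf_level)/2` (so a
#' 99% interval uses the 0.5% and 99.5% percentiles).  Reproducible under
#' `set.seed()`.
#'
#' @param points calibration points (as for [fit_calibration()]).
#' @param method fitting strategy.
#' @param n_boot number of resamples; at least 100 (a warning is issued below
#'   1000).
#' @param conf_level confidence level in (0, 1).
#' @return List with `slope_ci`, `intercept_ci`, `alpha`, `conf_level`,
#'   `n_boot`, `n_failed`, and the bootstrap replicate estimates in `boot`.
#' @export
bootstrap_ci <- function(points, method = "ols", n_boot = 1000,
                         conf_level = 0.95) {
  stopifnot(conf_level > 0, conf_level < 1)
  if (n_boot < 100) stop("'n_boot' must be at least 100")
  if (n_boot < 1000) {
    warning("n_boot below 1000; bootstrap intervals may be unstable")
  }
  xy <- .as_xy(points)
  n <- nrow(xy)
  # the fitter must succeed on the full data first
  .fit_core(xy$x, xy$y, method)
  alpha <- (1 - conf_level) / 2

  slopes <- numeric(n_boot)
  icpts <- numeric(n_boot)
  failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    est <- tryCatch(.fit_fast(xy$x[idx], xy$y[idx], method),
                    error = function(e) NULL)
    if (is.null(est)) {
      failed <- failed + 1L
      slopes[b] <- NA_real_; icpts[b] <- NA_real_
    } else {
      slopes[b] <- est[["slope"]]; icpts[b] <- est[["intercept"]]
    }
  }
  if (failed > 0.1 * n_boot) {
    stop("bootstrap unstable: fitter failed on ", failed, " of ", n_boot,
         " resamples")
  }
  list(slope_ci = unname(stats::quantile(slopes, c(alpha, 1 - alpha),
                                         na.rm = TRUE)),
       intercept_ci = unname(stats::quantile(icpts, c(alpha, 1 - alpha),
                                             na.rm = TRUE)),
       alpha = alpha, conf_level = conf_level, n_boot = n_boot,
       n_failed = failed,
       boot = data.frame(slope = slopes, intercept = icpts))
}

# Minimal fast fitters for bootstrap loops: no formula interface, no
# diagnostics, just slope and intercept.
.fit_fast <- function(x, y, method) {
  switch(method,
    ols = {
      if (length(unique(x)) < 2L) stop("degenerate resample")
      cf <- stats::.lm.fit(cbind(1, x), y)$coefficients
      c(intercept = cf[1L], slope = cf[2L])
    },
    wls = {
      if (any(x == 0)) stop("zero concentration in weighted resample")
      if (length(unique(x)) < 2L) stop("degenerate resample")
      sw <- 1 / x
      cf <- stats::.lm.fit(cbind(sw, sw * x), sw * y)$coefficients
      c(intercept = cf[1L], slope = cf[2L])
    },
    log = {
      if (any(x <= 0) || any(y <= 0)) stop("non-positive value in log resample")
      if (length(unique(x)) < 2L) stop("degenerate resample")
      cf <- stats::.lm.fit(cbind(1, log10(x)), log10(y))$coefficients
      c(intercept = cf[1L], slope = cf[2L])
    },
    lms = , lts = {
      core <- .fit_pair_search(x, y, variant = method)
      c(intercept = core$intercept, slope = core$slope)
    },
    mm = , wmm = {
      core <- .fit_mm(x, y, weights = if (method == "wmm") 1 / x^2 else NULL)
      c(intercept = core$intercept, slope = core$slope)
    },
    stop("unknown method: ", method))
}
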