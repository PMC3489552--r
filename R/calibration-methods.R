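# S3 methods for calibration_fit objects.

#' @export
print.calibration_fit <- function(x, digits = 4, ...) {
  space <- if (x$method == "log") " (log10 space)" else ""
  cat("Calibration fit [", x$method, "]", space, "\n", sep = "")
  cat("  slope:          ", format(x$slope, digits = digits), "\n")
  cat("  intercept:      ", format(x$intercept, digits = digits),
      if (x$method == "log") "" else " fmol/uL", "\n", sep = "")
  cat("  residual scale: ", format(x$residual_scale, digits = digits), "\n")
  cat("  R-squared:      ", format(x$r_squared, digits = digits), "\n")
  cat("  n points:       ", x$n_points, "\n")
  invisible(x)
}

#' @export
summary.calibration_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.calibration_fit")
}

#' @export
print.summary.calibration_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  if (f$ci_method != "none") {
    lvl <- format(100 * f$conf_level)
    cat("  ", lvl, "% CI slope:     [",
        format(f$slope_ci[1], digits = digits), ", ",
        format(f$slope_ci[2], digits = digits), "]  (", f$ci_method, ")\n",
        sep = "")
    cat("  ", lvl, "% CI intercept: [",
        format(f$intercept_ci[1], digits = digits), ", ",
        format(f$intercept_ci[2], digits = digits), "]\n", sep = "")
    contains1 <- !anyNA(f$slope_ci) &&
      f$slope_ci[1] <= 1 && 1 <= f$slope_ci[2]
    cat("  slope CI contains the ideal slope 1:",
        if (contains1) "yes" else "no", "\n")
  }
  if (f$weighting != "none") cat("  weighting: ", f$weighting, "\n", sep = "")
  if (f$n_blanks_excluded > 0) {
    cat("  blanks excluded:", f$n_blanks_excluded, "\n")
  }
  for (nt in f$notes) cat("  note:", nt, "\n")
  cat("  R-squared does not indicate the robustness of the fit;\n",
      "  inspect the slope/intercept intervals and residuals as well.\n",
      sep = "")
  invisible(x)
}

#' @export
coef.calibration_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
confint.calibration_fit <- function(object, parm, level, ...) {
  out <- rbind(intercept = object$intercept_ci, slope = object$slope_ci)
  colnames(out) <- paste0(100 * c((1 - object$conf_level) / 2,
                                  1 - (1 - object$conf_level) / 2), " %")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Predict measured concentrations from a calibration fit
#'
#' For linear-space fits returns `intercept + slope * x`; for the log-space
#' fit returns `10^(intercept + slope * log10(x))`, i.e. predictions are
#' always on the measured-concentration scale.
#'
#' @param object a `calibration_fit`.
#' @param newdata numeric vector of theoretical concentrations, or a data
#'   frame with a `theoretical_conc` column; defaults to the fitting data.
#' @param ... unused.
#' @export
predict.calibration_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) {
    object$data$x
  } else if (is.data.frame(newdata)) {
    newdata$theoretical_conc
  } else {
    as.numeric(newdata)
  }
  if (object$method == "log") {
    10^(object$intercept + object$slope * log10(x))
  } else {
    object$intercept + object$slope * x
  }
}

#' @export
residuals.calibration_fit <- function(object, ...) object$residuals

#' @export
fitted.calibration_fit <- function(object, ...) object$fitted

#' Plot a calibration fit
#'
#' Scatter of measured vs theoretical concentration with the fitted line.
#' With `loglog = TRUE` both axes are log-scaled, which accommodates the
#' wide concentration ranges typical of MRM calibration curves (a
#' linear-space fitted line then appears curved).
#'
#' @param x a `calibration_fit`.
#' @param loglog logical; plot on log-log axes.
#' @param ... passed to [plot()].
#' @export
plot.calibration_fit <- function(x, loglog = FALSE, ...) {
  d <- x$data
  if (x$method == "log") {
    graphics::plot(d$x, d$y, log = "xy",
                   xlab = "theoretical conc (fmol/uL)",
                   ylab = "measured conc (fmol/uL)", ...)
    xs <- exp(seq(log(min(d$x)), log(max(d$x)), length.out = 100))
    graphics::lines(xs, predict(x, xs), col = 2)
  } else if (loglog) {
    pos <- d$x > 0 & d$y > 0
    graphics::plot(d$x[pos], d$y[pos], log = "xy",
                   xlab = "theoretical conc (fmol/uL)",
                   ylab = "measured conc (fmol/uL)", ...)
    xs <- exp(seq(log(min(d$x[pos])), log(max(d$x[pos])), length.out = 100))
    graphics::lines(xs, pmax(predict(x, xs), .Machine$double.xmin), col = 2)
  } else {
    graphics::plot(d$x, d$y, xlab = "theoretical conc (fmol/uL)",
                   ylab = "measured conc (fmol/uL)", ...)
    graphics::abline(x$intercept, x$slope, col = 2)
  }
  invisible(x)
}
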