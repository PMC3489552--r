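# Intra- and interlaboratory precision summaries.
#
# CV = standard deviation / mean, always computed on the original (linear)
# concentration scale.

.cv <- function(v) stats::sd(v) / mean(v)

#' Intralaboratory CV per concentration level
#'
#' Coefficient of variation of the measured concentrations across replicates
#' for every (site, level) cell of one transition.  Cells with a single
#' replicate are omitted with a warning.
#'
#' @param ds a `transition_dataset`.
#' @param peptide,transition identifiers selecting the transition.
#' @param study optional study-phase filter.
#' @return Data frame with columns `site_id`, `study_phase`,
#'   `theoretical_conc`, `cv`, `n`.
#' @export
intra_lab_cv <- function(ds, peptide, transition, study = NULL) {
  pts <- calibration_points(ds, peptide, transition, study = study)
  pts <- pts[pts$sample_role != "blank", , drop = FALSE]
  key <- interaction(pts$site_id, pts$study_phase, pts$theoretical_conc,
                     drop = TRUE)
  cells <- split(pts, key)
  singles <- vapply(cells, nrow, integer(1)) < 2L
  if (any(singles)) {
    warning(sum(singles), " cell(s) with a single replicate omitted")
    cells <- cells[!singles]
  }
  out <- do.call(rbind, lapply(cells, function(d) {
    data.frame(site_id = d$site_id[1L], study_phase = d$study_phase[1L],
               theoretical_conc = d$theoretical_conc[1L],
               cv = .cv(d$measured_conc), n = nrow(d),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$site_id, out$study_phase, out$theoretical_conc), ]
  rownames(out) <- NULL
  out
}

#' Interlaboratory CV per concentration level
#'
#' Two summaries are reported side by side.  `median_of_site_cvs` is the
#' median over sites of the intralaboratory CVs at a level: it summarizes
#' precision but is blind to between-site accuracy (every site can be tight
#' around a different mean).  `pooled` is the CV of the pooled measurement
#' vector across all sites at a level, the convention of clinical
#' interlaboratory comparisons, which between-site mean shifts do inflate.
#'
#' @param ds a `transition_dataset` spanning at least 2 sites.
#' @param peptide,transition identifiers selecting the transition.
#' @param study optional study-phase filter.
#' @param mode `"both"` (default), `"median_of_site_cvs"` or `"pooled"`.
#' @return Data frame keyed by (`study_phase`, `theoretical_conc`) with the
#'   requested CV column(s) and `n_sites`.
#' @export
inter_lab_cv <- function(ds, peptide, transition, study = NULL,
                         mode = c("both", "median_of_site_cvs", "pooled")) {
  mode <- match.arg(mode)
  pts <- calibration_points(ds, peptide, transition, study = study)
  pts <- pts[pts$sample_role != "blank", , drop = FALSE]
  if (length(unique(pts$site_id)) < 2L) {
    stop("interlaboratory CV needs at least 2 sites")
  }
  key <- interaction(pts$study_phase, pts$theoretical_conc, drop = TRUE)
  out <- do.call(rbind, lapply(split(pts, key), function(d) {
    site_cvs <- vapply(split(d$measured_conc, d$site_id),
                       function(v) if (length(v) >= 2L) .cv(v) else NA_real_,
                       numeric(1))
    row <- data.frame(study_phase = d$study_phase[1L],
                      theoretical_conc = d$theoretical_conc[1L],
                      n_sites = length(unique(d$site_id)),
                      stringsAsFactors = FALSE)
    if (mode != "pooled") {
      row$median_of_site_cvs <- stats::median(site_cvs, na.rm = TRUE)
    }
    if (mode != "median_of_site_cvs") {
      row$pooled <- .cv(d$measured_conc)
    }
    row
  }))
  out <- out[order(out$study_phase, out$theoretical_conc), ]
  rownames(out) <- NULL
  out
}

#' Study-level precision summary
#'
#' Builds the study summary table for a multi-peptide (optionally
#' multi-site, multi-study) dataset.  Per peptide and study phase, a single
#' "best" transition is selected by lowest combined CV (the median of its
#' intralaboratory CVs across sites and levels); for that transition the
#' summary reports the median and range of intralaboratory CVs per site, the
#' interlaboratory CVs per level (both modes, when 2+ sites are present),
#' the calibration slope per site, and the percent recovery, computed as
#' 100 x the median over curve points of measured/theoretical concentration
#' (a slope-based variant, `100 x slope`, is also included for comparison).
#'
#' @param ds a `transition_dataset`.
#' @param regression calibration strategy for the reported slope.
#' @return Object of class `precision_summary`: list of data frames
#'   `best_transitions`, `intra`, `inter`, `regression`.
#' @export
summarize_study <- function(ds, regression = "ols") {
  stopifnot(inherits(ds, "transition_dataset"))
  r <- ds$records[ds$records$label == "analyte", ]
  combos <- unique(r[, c("study_phase", "peptide_id", "transition_id")])

  # combined CV per transition: median intra-lab CV over sites x levels
  combos$combined_cv <- vapply(seq_len(nrow(combos)), function(i) {
    tab <- suppressWarnings(
      intra_lab_cv(ds, combos$peptide_id[i], combos$transition_id[i],
                   study = combos$study_phase[i]))
    stats::median(tab$cv)
  }, numeric(1))

  best <- do.call(rbind, lapply(
    split(combos, interaction(combos$study_phase, combos$peptide_id,
                              drop = TRUE)),
    function(d) d[which.min(d$combined_cv), ]))
  rownames(best) <- NULL

  intra <- list(); inter <- list(); regr <- list()
  for (i in seq_len(nrow(best))) {
    pep <- best$peptide_id[i]; tr <- best$transition_id[i]
    st <- best$study_phase[i]
    tab <- suppressWarnings(intra_lab_cv(ds, pep, tr, study = st))
    intra[[i]] <- do.call(rbind, lapply(split(tab, tab$site_id), function(d) {
      data.frame(study_phase = st, peptide_id = pep, transition_id = tr,
                 site_id = d$site_id[1L],
                 intra_cv_median = stats::median(d$cv),
                 intra_cv_min = min(d$cv), intra_cv_max = max(d$cv),
                 stringsAsFactors = FALSE)
    }))
    n_sites <- length(unique(tab$site_id))
    if (n_sites >= 2L) {
      it <- inter_lab_cv(ds, pep, tr, study = st)
      it$peptide_id <- pep; it$transition_id <- tr
      inter[[i]] <- it
    }
    regr[[i]] <- do.call(rbind, lapply(unique(tab$site_id), function(site) {
      pts <- calibration_points(ds, pep, tr, site = site, study = st)
      fit <- fit_calibration(pts, method = regression, ci = "none")
      curve <- pts[pts$sample_role != "blank", ]
      rec <- 100 * stats::median(curve$measured_conc /
                                   curve$theoretical_conc)
      data.frame(study_phase = st, peptide_id = pep, transition_id = tr,
                 site_id = site, linear_slope = fit$slope,
                 pct_recovery = rec, pct_recovery_slope = 100 * fit$slope,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- structure(list(best_transitions = best,
                        intra = do.call(rbind, intra),
                        inter = if (length(inter)) do.call(rbind, inter)
                                else NULL,
                        regression = do.call(rbind, regr)),
                   class = "precision_summary")
  rownames(out$intra) <- NULL
  rownames(out$regression) <- NULL
  out
}

#' @export
print.precision_summary <- function(x, digits = 3, ...) {
  cat("Precision summary\n")
  cat("Best transitions (lowest combined CV):\n")
  print(format(x$best_transitions, digits = digits), row.names = FALSE)
  cat("\nIntralaboratory CV (median [min-max]) per site:\n")
  print(format(x$intra, digits = digits), row.names = FALSE)
  if (!is.null(x$inter)) {
    cat("\nInterlaboratory CV per level:\n")
    print(format(x$inter, digits = digits), row.names = FALSE)
  }
  cat("\nCalibration slope and % recovery per site:\n")
  print(format(x$regression, digits = digits), row.names = FALSE)
  invisible(x)
}
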