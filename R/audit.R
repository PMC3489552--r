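# AuDIT: automated detection of inaccurate and imprecise transitions.
#
# Interference in a transition perturbs its relative (branching) ratio to
# the other transitions of the same precursor for the analyte but not for
# the chemically identical SIS. AuDIT tests analyte vs SIS relative ratios
# per transition pair (Welch t), corrects across the run (Benjamini-
# Hochberg), combines each transition's dependent pair p-values, and
# additionally filters on the CV of the peak-area ratio. A transition is
# "bad" if the corrected combined p-value falls below the p-value threshold
# (default 1e-5) or the PAR CV exceeds the CV threshold (default 0.2).

#' Relative (branching) ratios between transitions
#'
#' Computes per-replicate relative ratios of transition peak areas for one
#' peptide and label.  `"minimal_pairs"` pairs each transition with one
#' other via the cyclic pairing over transitions sorted by `transition_id`
#' (1 with 2, ..., last with first), so that each transition enters exactly
#' 2 ratios; `"all_pairs"` emits every unordered pair once, so each
#' transition enters `n - 1` ratios.  With only 2 transitions both schemes
#' give the single pair.
#'
#' @param areas numeric matrix of peak areas, rows = replicates, columns =
#'   transitions (column names = transition ids); all areas must be
#'   positive.
#' @param scheme `"minimal_pairs"` or `"all_pairs"`.
#' @param label which isotope label the areas belong to (bookkeeping tag).
#' @return Object of class `ratio_set`: list with `scheme`, `pairs` (data
#'   frame of numerator/denominator transition ids), `ratios` (matrix,
#'   replicates x pairs) and `label`.
#' @export
relative_ratios <- function(areas, scheme = c("minimal_pairs", "all_pairs"),
                            label = "analyte") {
  scheme <- match.arg(scheme)
  areas <- as.matrix(areas)
  if (is.null(colnames(areas))) {
    colnames(areas) <- paste0("T", seq_len(ncol(areas)))
  }
  if (ncol(areas) < 2L) stop("need at least 2 transitions to form ratios")
  zero <- colSums(!is.na(areas) & areas <= 0) > 0
  if (any(zero)) {
    stop("undefined relative ratio: non-positive peak area in transition(s) ",
         paste(colnames(areas)[zero], collapse = ", "))
  }
  areas <- areas[, order(colnames(areas)), drop = FALSE]
  n <- ncol(areas)
  if (scheme == "minimal_pairs" && n > 2L) {
    i <- seq_len(n)
    j <- c(seq_len(n)[-1L], 1L)
  } else {
    pr <- utils::combn(n, 2L)
    i <- pr[1L, ]; j <- pr[2L, ]
  }
  ratios <- areas[, i, drop = FALSE] / areas[, j, drop = FALSE]
  pair_id <- paste(colnames(areas)[i], colnames(areas)[j], sep = "/")
  colnames(ratios) <- pair_id
  structure(list(scheme = scheme,
                 pairs = data.frame(numerator = colnames(areas)[i],
                                    denominator = colnames(areas)[j],
                                    pair = pair_id,
                                    stringsAsFactors = FALSE),
                 ratios = ratios, label = label),
            class = "ratio_set")
}

#' Per-pair analyte-vs-SIS ratio t-tests
#'
#' For each transition pair, applies a two-sided Welch t-test to the
#' hypothesis that the analyte relative ratios differ from the SIS relative
#' ratios across replicates.  Degenerate inputs (both sides constant) give
#' p = 1 when the constants agree and p = 0 (flagged) when they differ.
#'
#' @param analyte_ratios,sis_ratios matching `ratio_set` objects from
#'   [relative_ratios()].
#' @param log_ratio test log-transformed ratios instead of raw ratios.
#' @return Data frame with columns `pair`, `p_value`, `degenerate`.
#' @export
ratio_pvalues <- function(analyte_ratios, sis_ratios, log_ratio = FALSE) {
  stopifnot(inherits(analyte_ratios, "ratio_set"),
            inherits(sis_ratios, "ratio_set"))
  if (!identical(analyte_ratios$pairs$pair, sis_ratios$pairs$pair)) {
    stop("analyte and SIS ratio sets cover different transition pairs")
  }
  pairs <- analyte_ratios$pairs$pair
  if (min(nrow(analyte_ratios$ratios), nrow(sis_ratios$ratios)) < 3L) {
    warning("fewer than 3 replicates per side; ratio t-tests are unreliable")
  }
  p <- numeric(length(pairs))
  degen <- logical(length(pairs))
  for (k in seq_along(pairs)) {
    a <- analyte_ratios$ratios[, k]
    s <- sis_ratios$ratios[, k]
    if (log_ratio) { a <- log(a); s <- log(s) }
    if (stats::var(a) == 0 && stats::var(s) == 0) {
      degen[k] <- TRUE
      p[k] <- if (isTRUE(all.equal(mean(a), mean(s)))) 1 else 0
    } else {
      p[k] <- stats::t.test(a, s, var.equal = FALSE)$p.value
    }
  }
  data.frame(pair = pairs, p_value = p, degenerate = degen,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values (a thin,
#' domain-checked wrapper around [stats::p.adjust()]); applied across all
#' ratio-level p-values of an AuDIT run.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return Adjusted p-values (monotone, capped at 1).
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

# Kost-McDermott cubic approximation to cov(-2 ln p_i, -2 ln p_j) as a
# function of the correlation of the underlying statistics.
.brown_cov <- function(rho) {
  rho <- pmin(1, pmax(-1, rho))
  3.263 * rho + 0.710 * rho^2 + 0.027 * rho^3
}

#' Combine dependent p-values for one transition
#'
#' Each transition's ratio p-values share peak areas and are therefore
#' dependent.  The default combiner is Fisher's statistic
#' `X = -2 sum(log p)` with the Brown-Kost moment correction: `X` is
#' referred to a scaled chi-squared distribution whose scale and degrees of
#' freedom are matched to `E[X] = 2k` and a variance inflated by the
#' pairwise correlations of the underlying statistics (perfectly correlated
#' copies of one p-value collapse back to that p-value).  Alternatives:
#' `"sidak"` (Sidak-corrected minimum p) and `"stouffer"`
#' (correlation-adjusted mean z).
#'
#' @param pvalues p-values for one transition (already BH-adjusted in the
#'   AuDIT pipeline).
#' @param rho correlation matrix (k x k) of the underlying statistics, or
#'   `NULL` for independence.
#' @param method `"brown"`, `"sidak"` or `"stouffer"`.
#' @return A single combined p-value in \[0, 1\].
#' @export
combine_dependent_pvalues <- function(pvalues, rho = NULL,
                                      method = c("brown", "sidak",
                                                 "stouffer")) {
  method <- match.arg(method)
  if (length(pvalues) == 0L) stop("no p-values to combine")
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  k <- length(pvalues)
  if (k == 1L) return(pvalues)
  if (is.null(rho)) rho <- diag(k)
  stopifnot(is.matrix(rho), nrow(rho) == k, ncol(rho) == k)

  if (method == "sidak") {
    return(1 - (1 - min(pvalues))^k)
  }
  if (method == "stouffer") {
    z <- stats::qnorm(pmax(pmin(pvalues, 1 - 1e-16), 1e-300),
                      lower.tail = FALSE)
    vsum <- k + 2 * sum(rho[upper.tri(rho)])
    vsum <- max(vsum, 1e-8)
    return(stats::pnorm(sum(z) / sqrt(vsum), lower.tail = FALSE))
  }
  # Brown-Kost corrected Fisher
  pv <- pmax(pvalues, 1e-300)
  x <- -2 * sum(log(pv))
  e <- 2 * k
  v <- 4 * k + 2 * sum(.brown_cov(rho[upper.tri(rho)]))
  v <- max(v, 1e-8)
  cc <- v / (2 * e)
  df <- 2 * e^2 / v
  stats::pchisq(x / cc, df = df, lower.tail = FALSE)
}

#' @importFrom stats pnorm
NULL

#' Coefficient of variation of the peak-area ratio
#'
#' Sample standard deviation divided by the mean of the PARs across all
#' replicates of one transition in one sample.
#'
#' @param par_values at least 2 peak-area ratios.
#' @return Non-negative CV.
#' @export
par_cv <- function(par_values) {
  par_values <- par_values[!is.na(par_values)]
  if (length(par_values) < 2L) stop("PAR CV needs at least 2 replicates")
  m <- mean(par_values)
  if (m == 0) stop("undefined CV: mean PAR is 0")
  stats::sd(par_values) / m
}

#' Classify transitions as good or bad
#'
#' A transition is "bad" if its corrected combined p-value is below
#' `p_threshold` (default 1e-5) or its PAR CV exceeds `cv_threshold`
#' (default 0.2); otherwise it is "good".  `reason` records which
#' condition(s) fired.
#'
#' @param combined_p,par_cv numeric vectors (recycled to equal length).
#' @param p_threshold,cv_threshold decision thresholds.
#' @return Data frame with columns `combined_p`, `par_cv`, `flag`
#'   (`"good"`/`"bad"`) and `reason` (`""`, `"pvalue"`, `"cv"` or
#'   `"pvalue+cv"`).
#' @export
classify_transitions <- function(combined_p, par_cv, p_threshold = 1e-5,
                                 cv_threshold = 0.2) {
  stopifnot(p_threshold > 0, p_threshold < 1, cv_threshold > 0)
  nn <- max(length(combined_p), length(par_cv))
  combined_p <- rep_len(combined_p, nn)
  par_cv <- rep_len(par_cv, nn)
  p_bad <- combined_p < p_threshold
  cv_bad <- par_cv > cv_threshold
  reason <- ifelse(p_bad & cv_bad, "pvalue+cv",
                   ifelse(p_bad, "pvalue", ifelse(cv_bad, "cv", "")))
  data.frame(combined_p = combined_p, par_cv = par_cv,
             flag = ifelse(p_bad | cv_bad, "bad", "good"),
             reason = reason, stringsAsFactors = FALSE)
}

# Build replicate-aligned area matrices (replicates x transitions) for one
# (site, study, peptide, sample) group and label.
.area_matrix <- function(rec) {
  trans <- sort(unique(rec$transition_id))
  reps <- sort(unique(rec$replicate))
  m <- matrix(NA_real_, nrow = length(reps), ncol = length(trans),
              dimnames = list(NULL, trans))
  m[cbind(match(rec$replicate, reps), match(rec$transition_id, trans))] <-
    rec$peak_area
  m
}

#' Run AuDIT on a transition dataset
#'
#' Executes the full pipeline per (site, study, peptide, sample) group:
#' relative ratios for analyte and SIS, Welch t-tests per pair,
#' Benjamini-Hochberg correction across all ratio p-values of the run,
#' dependent combination per transition, PAR CV filter, and good/bad
#' classification.  Samples are audited independently; blanks are skipped
#' (their analyte signal is noise and yields no meaningful ratios), as are
#' peptides monitored with a single transition.
#'
#' @param ds a `transition_dataset`.
#' @param scheme ratio scheme, `"minimal_pairs"` (default) or
#'   `"all_pairs"`.
#' @param p_threshold,cv_threshold decision thresholds (defaults 1e-5 and
#'   0.2).
#' @param combine dependent p-value combiner (see
#'   [combine_dependent_pvalues()]).
#' @param log_ratio run the t-tests on log ratios.
#' @return Data frame (one row per site/study/peptide/sample/transition)
#'   with `combined_p`, `par_cv`, `flag`, `reason`; thresholds stored in
#'   attributes.
#' @export
audit_transitions <- function(ds, scheme = c("minimal_pairs", "all_pairs"),
                              p_threshold = 1e-5, cv_threshold = 0.2,
                              combine = "brown", log_ratio = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(ds, "transition_dataset"))
  r <- ds$records
  r <- r[r$sample_role != "blank", , drop = FALSE]
  key <- paste(r$site_id, r$study_phase, r$peptide_id, r$sample_id,
               sep = "\r")
  groups <- split(seq_len(nrow(r)), key)

  rows <- list()      # per-transition bookkeeping
  pvals <- list()     # per-pair p-values across the whole run
  gi <- 0L
  for (idx in groups) {
    g <- r[idx, , drop = FALSE]
    a_rec <- g[g$label == "analyte", ]
    s_rec <- g[g$label == "SIS", ]
    trans <- intersect(unique(a_rec$transition_id),
                       unique(s_rec$transition_id))
    if (length(trans) < 2L) next
    a_m <- .area_matrix(a_rec[a_rec$transition_id %in% trans, ])
    s_m <- .area_matrix(s_rec[s_rec$transition_id %in% trans, ])
    # ratios are undefined for non-positive areas: drop transitions with no
    # usable signal, then replicates still containing non-positive values
    usable <- colSums(is.na(a_m) | a_m <= 0) < nrow(a_m) / 2 &
      colSums(is.na(s_m) | s_m <= 0) < nrow(s_m) / 2
    if (sum(usable) < 2L) next
    a_m <- a_m[, usable, drop = FALSE]
    s_m <- s_m[, usable, drop = FALSE]
    ok_rep <- rowSums(is.na(a_m) | a_m <= 0 | is.na(s_m) | s_m <= 0) == 0
    if (sum(ok_rep) < 2L) next
    a_m <- a_m[ok_rep, , drop = FALSE]
    s_m <- s_m[ok_rep, , drop = FALSE]
    ars <- relative_ratios(a_m, scheme = scheme, label = "analyte")
    srs <- relative_ratios(s_m, scheme = scheme, label = "SIS")
    pv <- ratio_pvalues(ars, srs, log_ratio = log_ratio)

    gi <- gi + 1L
    pvals[[gi]] <- pv$p_value
    par_m <- a_m / s_m * 1  # PAR per replicate and transition
    rows[[gi]] <- list(meta = g[1L, c("site_id", "study_phase",
                                      "peptide_id", "sample_id")],
                       pairs = ars$pairs, ratios_a = ars$ratios,
                       ratios_s = srs$ratios, par = par_m,
                       transitions = colnames(a_m))
  }
  if (gi == 0L) stop("no auditable groups (need >= 2 transitions per peptide)")

  # BH across every ratio p-value of the run
  all_p <- unlist(pvals[seq_len(gi)])
  adj <- bh_adjust(all_p)
  offsets <- cumsum(c(0L, lengths(pvals[seq_len(gi)])))

  out <- list()
  for (g in seq_len(gi)) {
    info <- rows[[g]]
    adj_g <- adj[(offsets[g] + 1L):offsets[g + 1L]]
    for (tr in info$transitions) {
      in_pair <- info$pairs$numerator == tr | info$pairs$denominator == tr
      pk <- adj_g[in_pair]
      rho <- .ratio_correlation(info$ratios_a[, in_pair, drop = FALSE],
                                info$ratios_s[, in_pair, drop = FALSE])
      cp <- combine_dependent_pvalues(pk, rho = rho, method = combine)
      cv <- par_cv(info$par[, tr])
      out[[length(out) + 1L]] <- cbind(info$meta,
        data.frame(transition_id = tr, combined_p = cp, par_cv = cv,
                   stringsAsFactors = FALSE))
    }
  }
  res <- do.call(rbind, out)
  cls <- classify_transitions(res$combined_p, res$par_cv,
                              p_threshold = p_threshold,
                              cv_threshold = cv_threshold)
  res$flag <- cls$flag
  res$reason <- cls$reason
  rownames(res) <- NULL
  attr(res, "p_threshold") <- p_threshold
  attr(res, "cv_threshold") <- cv_threshold
  attr(res, "scheme") <- scheme
  attr(res, "combine") <- combine
  res
}

# Empirical correlation of the ratio design: correlate the centered
# within-label log-ratio replicate vectors of each pair.
.ratio_correlation <- function(ratios_a, ratios_s) {
  k <- ncol(ratios_a)
  if (k == 1L) return(matrix(1, 1, 1))
  v <- rbind(sweep(log(ratios_a), 2, colMeans(log(ratios_a))),
             sweep(log(ratios_s), 2, colMeans(log(ratios_s))))
  rho <- suppressWarnings(stats::cor(v))
  rho[!is.finite(rho)] <- 0
  diag(rho) <- 1
  rho
}

#' Contingency metrics for good/bad calls
#'
#' Builds the 2x2 contingency summary used to evaluate AuDIT against expert
#' annotation, with a *positive* defined as a "good" transition call:
#' accuracy = (TP+TN)/total, sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP).  Percentages are also reported rounded to the nearest
#' integer.
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return Object of class `contingency_summary`.
#' @export
contingency_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  acc <- (tp + tn) / total
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = acc, sensitivity = sens, specificity = spec,
                 accuracy_pct = round(100 * acc),
                 sensitivity_pct = round(100 * sens),
                 specificity_pct = round(100 * spec)),
            class = "contingency_summary")
}

#' @export
print.contingency_summary <- function(x, ...) {
  cat("Contingency summary (positive = 'good' call)\n")
  cat(sprintf("  TN %d  TP %d  FN %d  FP %d\n", x$tn, x$tp, x$fn, x$fp))
  cat(sprintf("  accuracy %d%%  sensitivity %d%%  specificity %d%%\n",
              x$accuracy_pct, x$sensitivity_pct, x$specificity_pct))
  invisible(x)
}

#' Evaluate AuDIT calls against expert annotation
#'
#' Joins AuDIT results with a truth table of good/bad annotations and
#' returns the 2x2 contingency summary (positive = "good" call).
#'
#' @param results data frame from [audit_transitions()].
#' @param truth data frame with an `annotation` column (`"good"`/`"bad"`)
#'   and any subset of the key columns `site_id`, `study_phase`,
#'   `peptide_id`, `sample_id`, `transition_id`; results are matched on the
#'   keys present.
#' @return A `contingency_summary`.
#' @export
evaluate_against_annotation <- function(results, truth) {
  stopifnot(is.data.frame(results), is.data.frame(truth))
  if (!"annotation" %in% names(truth)) {
    stop("'truth' must have an 'annotation' column with good/bad labels")
  }
  keys <- intersect(c("site_id", "study_phase", "peptide_id", "sample_id",
                      "transition_id"), names(truth))
  if (length(keys) == 0L) stop("'truth' shares no key columns with results")
  m <- merge(results, truth[, c(keys, "annotation")], by = keys,
             all.x = TRUE, sort = FALSE)
  un <- is.na(m$annotation)
  if (any(un)) {
    miss <- unique(do.call(paste, c(m[un, keys, drop = FALSE], sep = "/")))
    stop("no annotation for: ",
         paste(utils::head(miss, 5L), collapse = "; "),
         if (length(miss) > 5L) " ..." else "")
  }
  if (!all(m$annotation %in% c("good", "bad"))) {
    stop("annotation values must be 'good' or 'bad'")
  }
  tp <- sum(m$flag == "good" & m$annotation == "good")
  tn <- sum(m$flag == "bad" & m$annotation == "bad")
  fp <- sum(m$flag == "good" & m$annotation == "bad")
  fn <- sum(m$flag == "bad" & m$annotation == "good")
  contingency_metrics(tp, tn, fp, fn)
}

#' ROC of the AuDIT p-value threshold
#'
#' Sweeps the p-value threshold from 0 to 1 at a fixed CV threshold,
#' recomputing sensitivity and specificity against annotation at each
#' threshold, and reports the trapezoidal area under the ROC curve.
#'
#' @param results data frame from [audit_transitions()] (uses its
#'   `combined_p` and `par_cv` columns).
#' @param truth annotation table as for [evaluate_against_annotation()].
#' @param cv_threshold fixed CV threshold (default 0.2).
#' @param thresholds p-value thresholds to evaluate; defaults to the
#'   observed combined p-values plus the endpoints.
#' @return List with `table` (threshold, sensitivity, specificity) and
#'   `auc`.
#' @export
audit_roc <- function(results, truth, cv_threshold = 0.2,
                      thresholds = NULL) {
  keys <- intersect(c("site_id", "study_phase", "peptide_id", "sample_id",
                      "transition_id"), names(truth))
  m <- merge(results, truth[, c(keys, "annotation")], by = keys,
             all.x = TRUE, sort = FALSE)
  if (anyNA(m$annotation)) stop("unannotated transitions in ROC evaluation")
  if (is.null(thresholds)) {
    thresholds <- sort(unique(c(0, m$combined_p, 1)))
  }
  tab <- do.call(rbind, lapply(thresholds, function(thr) {
    good <- !(m$combined_p < thr | m$par_cv > cv_threshold)
    tp <- sum(good & m$annotation == "good")
    tn <- sum(!good & m$annotation == "bad")
    fp <- sum(good & m$annotation == "bad")
    fn <- sum(!good & m$annotation == "good")
    data.frame(threshold = thr,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA)
  }))
  ok <- stats::complete.cases(tab[, c("sensitivity", "specificity")])
  fpr <- 1 - tab$specificity[ok]
  tpr <- tab$sensitivity[ok]
  o <- order(fpr, tpr)
  fpr <- c(0, fpr[o], 1); tpr <- c(0, tpr[o], 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(table = tab, auc = auc)
}

#' @importFrom utils tail
NULL
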