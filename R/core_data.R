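# Data model and elementary SID quantification arithmetic.
#
# A transition dataset is a long table: one row per measured peak area for
# (site, study phase, protein, peptide, transition, isotope label, sample,
# replicate), plus the assay-wide (or per-peptide) concentration at which the
# stable isotope-labeled standard (SIS) was spiked.

.TRANSITION_FIELDS <- c("site_id", "study_phase", "protein_id", "peptide_id",
                        "transition_id", "label", "sample_id", "sample_role",
                        "theoretical_conc", "replicate", "peak_area",
                        "retention_time")

.MANDATORY_FIELDS <- c("peptide_id", "transition_id", "label", "sample_id",
                       "theoretical_conc", "replicate", "peak_area")

.NUMERIC_FIELDS <- c("theoretical_conc", "replicate", "peak_area",
                     "retention_time")

.LABEL_SYNONYMS <- c(analyte = "analyte", light = "analyte", endo = "analyte",
                     endogenous = "analyte", l = "analyte",
                     sis = "SIS", heavy = "SIS", standard = "SIS",
                     h = "SIS", "internal standard" = "SIS")

#' Construct a transition dataset
#'
#' Assembles a validated container of transition-level peak areas together
#' with the SIS spike concentration.  Missing optional columns (`site_id`,
#' `study_phase`, `protein_id`, `sample_role`, `retention_time`) are filled
#' with defaults; `sample_role` is inferred as `"blank"` where
#' `theoretical_conc == 0` and `"curve_point"` otherwise.  Content problems
#' (negative areas, duplicated keys, missing SIS partners) are *not* errors
#' here; they are enumerated by [validate_dataset()].
#'
#' @param records data frame with at least the columns `peptide_id`,
#'   `transition_id`, `label` (`"analyte"`/`"SIS"`, common vendor synonyms
#'   such as `"light"`/`"heavy"` are normalized), `sample_id`,
#'   `theoretical_conc` (fmol/uL, 0 for blanks), `replicate`, `peak_area`.
#' @param sis_conc SIS spike concentration in fmol/uL; a single positive
#'   number for the whole assay or a named vector keyed by `peptide_id`.
#' @return An object of class `transition_dataset`: a list with elements
#'   `records` (canonicalized data frame) and `sis_conc`.
#' @seealso [read_transition_table()], [validate_dataset()],
#'   [calibration_points()]
#' @export
transition_dataset <- function(records, sis_conc = 50) {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.MANDATORY_FIELDS, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(sis_conc) || any(sis_conc <= 0) || anyNA(sis_conc)) {
    stop("'sis_conc' must be positive (fmol/uL)")
  }

  records$label <- .normalize_label(records$label)
  for (fld in intersect(.NUMERIC_FIELDS, names(records))) {
    records[[fld]] <- .parse_numeric(records[[fld]], fld)
  }
  if (is.null(records$site_id)) records$site_id <- "site1"
  if (is.null(records$study_phase)) records$study_phase <- "other"
  bad_phase <- !records$study_phase %in% c("I", "II", "III", "other")
  if (any(bad_phase)) {
    stop("invalid study_phase value(s): ",
         paste(unique(records$study_phase[bad_phase]), collapse = ", "))
  }
  if (is.null(records$protein_id)) records$protein_id <- NA_character_
  if (is.null(records$sample_role)) {
    records$sample_role <-
      ifelse(records$theoretical_conc == 0, "blank", "curve_point")
  }
  bad_role <- !records$sample_role %in% c("blank", "curve_point", "unknown")
  if (any(bad_role)) {
    stop("invalid sample_role value(s): ",
         paste(unique(records$sample_role[bad_role]), collapse = ", "))
  }
  if (is.null(records$retention_time)) records$retention_time <- NA_real_

  extra <- setdiff(names(records), .TRANSITION_FIELDS)
  records <- records[, c(.TRANSITION_FIELDS, extra), drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, sis_conc = sis_conc),
            class = "transition_dataset")
}

.normalize_label <- function(x) {
  x <- as.character(x)
  key <- tolower(trimws(x))
  out <- unname(.LABEL_SYNONYMS[key])
  unknown <- is.na(out)
  if (any(unknown)) {
    stop("unrecognized isotope label value(s): ",
         paste(unique(x[unknown]), collapse = ", "),
         " (expected analyte/SIS or light/heavy)")
  }
  out
}

.parse_numeric <- function(x, field) {
  if (is.numeric(x)) return(as.numeric(x))
  was_na <- is.na(x) | trimws(as.character(x)) == ""
  out <- suppressWarnings(as.numeric(as.character(x)))
  bad <- is.na(out) & !was_na
  if (any(bad)) {
    stop("unparseable numeric value in column '", field, "' at row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  out
}

#' Read a transition results table
#'
#' Parses a delimited text export (comma- or tab-separated, with header) of
#' transition-level peak areas, such as the "transition results" tables
#' produced by common MRM-MS analysis software, into a
#' [transition_dataset()].  A `column_map` adapts vendor header vocabularies
#' (e.g. `Area`, `Replicate Name`, `Isotope Label`) to the canonical field
#' names; unknown columns are carried along untouched.
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param column_map named character vector mapping canonical field names to
#'   file column names, e.g. `c(peak_area = "Area", label = "Isotope Label")`.
#'   Fields not mentioned are looked up under their canonical names.
#' @param sis_conc SIS spike concentration (fmol/uL), scalar or named by
#'   peptide.
#' @param sep field separator; by default inferred from the file extension
#'   (`.tsv`/`.txt` are tab-separated, everything else comma-separated).
#' @return A `transition_dataset`.
#' @export
read_transition_table <- function(path, column_map = NULL, sis_conc = 50,
                                  sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.csv(path, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || any(names(column_map) == "")) {
      stop("'column_map' must be a named vector: canonical field -> file column")
    }
    absent <- setdiff(unname(column_map), names(raw))
    if (length(absent) > 0L) {
      stop("column_map refers to column(s) absent from the file: ",
           paste(absent, collapse = ", "))
    }
    for (fld in names(column_map)) {
      names(raw)[names(raw) == column_map[[fld]]] <- fld
    }
  }
  missing_cols <- setdiff(.MANDATORY_FIELDS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("input table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  transition_dataset(raw, sis_conc = sis_conc)
}

#' Write a transition dataset to a delimited file
#'
#' Inverse of [read_transition_table()]: a write-then-read round trip
#' reproduces all records.
#'
#' @param ds a `transition_dataset`.
#' @param path output path; `.tsv`/`.txt` extensions select tab separation.
#' @return `path`, invisibly.
#' @export
write_transition_table <- function(ds, path) {
  stopifnot(inherits(ds, "transition_dataset"))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(ds$records, path, sep = sep, row.names = FALSE,
                     quote = TRUE)
  invisible(path)
}

#' @export
print.transition_dataset <- function(x, ...) {
  r <- x$records
  cat("Transition dataset:", nrow(r), "records\n")
  cat("  peptides:   ", length(unique(r$peptide_id)),
      " | transitions: ", length(unique(paste(r$peptide_id, r$transition_id))),
      "\n", sep = "")
  cat("  sites:      ", length(unique(r$site_id)),
      " | samples: ", length(unique(r$sample_id)),
      " (", sum(tapply(r$sample_role == "blank", r$sample_id, any)),
      " blank)\n", sep = "")
  cat("  SIS conc:   ", paste(format(x$sis_conc), collapse = ", "),
      " fmol/uL\n", sep = "")
  invisible(x)
}

.record_key <- function(r) {
  paste(r$site_id, r$study_phase, r$peptide_id, r$transition_id,
        r$sample_id, r$replicate, sep = "\r")
}

#' Validate a transition dataset
#'
#' Enumerates every invariant violation without raising: negative peak areas
#' or concentrations, blanks with non-zero theoretical concentration,
#' duplicated (site, study, peptide, transition, sample, replicate, label)
#' keys, analyte records lacking a matching SIS partner, and SIS records with
#' non-positive peak area (which would make the peak-area ratio undefined).
#'
#' @param ds a `transition_dataset`.
#' @return An object of class `validation_report` with elements `n_records`,
#'   `missing_sis_pairs`, `duplicate_keys`, `negative_or_zero_sis_areas` and
#'   `warnings`.  The report is empty (see [print()] output or
#'   `is_valid()`-style check via `length`s) if and only if the dataset
#'   satisfies all invariants.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "transition_dataset"))
  r <- ds$records
  warnings <- character()

  if (any(r$peak_area < 0, na.rm = TRUE)) {
    warnings <- c(warnings, paste0("negative peak_area at row(s): ",
      paste(utils::head(which(r$peak_area < 0), 5L), collapse = ", ")))
  }
  if (any(r$theoretical_conc < 0, na.rm = TRUE)) {
    warnings <- c(warnings, paste0("negative theoretical_conc at row(s): ",
      paste(utils::head(which(r$theoretical_conc < 0), 5L), collapse = ", ")))
  }
  bad_blank <- r$sample_role == "blank" & r$theoretical_conc != 0
  if (any(bad_blank)) {
    warnings <- c(warnings,
      paste0("blank sample(s) with non-zero theoretical_conc: ",
             paste(unique(r$sample_id[bad_blank]), collapse = ", ")))
  }

  key <- paste(.record_key(r), r$label, sep = "\r")
  dup <- duplicated(key)
  duplicate_keys <- unique(r[dup, c("site_id", "study_phase", "peptide_id",
                                    "transition_id", "sample_id", "replicate",
                                    "label")])
  rownames(duplicate_keys) <- NULL

  a <- r[r$label == "analyte", , drop = FALSE]
  s <- r[r$label == "SIS", , drop = FALSE]
  unmatched <- !(.record_key(a) %in% .record_key(s))
  missing_sis_pairs <- unique(a[unmatched, c("site_id", "study_phase",
                                             "peptide_id", "transition_id",
                                             "sample_id", "replicate")])
  rownames(missing_sis_pairs) <- NULL

  bad_sis <- s$peak_area <= 0
  negative_or_zero_sis_areas <- unique(s[bad_sis, c("site_id", "study_phase",
                                                    "peptide_id",
                                                    "transition_id",
                                                    "sample_id", "replicate")])
  rownames(negative_or_zero_sis_areas) <- NULL

  structure(list(n_records = nrow(r),
                 missing_sis_pairs = missing_sis_pairs,
                 duplicate_keys = duplicate_keys,
                 negative_or_zero_sis_areas = negative_or_zero_sis_areas,
                 warnings = warnings),
            class = "validation_report")
}

#' Test whether a validation report is clean
#' @param report a `validation_report` from [validate_dataset()].
#' @return `TRUE` if no violations were recorded.
#' @export
report_is_clean <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  nrow(report$missing_sis_pairs) == 0L &&
    nrow(report$duplicate_keys) == 0L &&
    nrow(report$negative_or_zero_sis_areas) == 0L &&
    length(report$warnings) == 0L
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report over", x$n_records, "records:\n")
  if (report_is_clean(x)) {
    cat("  no invariant violations\n")
  } else {
    cat("  missing SIS partners:      ", nrow(x$missing_sis_pairs), "\n")
    cat("  duplicate keys:            ", nrow(x$duplicate_keys), "\n")
    cat("  non-positive SIS areas:    ", nrow(x$negative_or_zero_sis_areas),
        "\n")
    for (w in x$warnings) cat("  warning:", w, "\n")
  }
  invisible(x)
}

#' Peak area ratio (PAR)
#'
#' Divides the analyte transition peak area by the peak area of the matched
#' SIS transition.  The PAR is the elementary SID quantity: with the SIS
#' spiked at a fixed known concentration it is proportional to the analyte
#' concentration.
#'
#' @param analyte_area non-negative analyte peak area(s).
#' @param sis_area positive SIS peak area(s), recycled against
#'   `analyte_area`.
#' @param context optional character tag(s) (e.g. "peptide/transition/sample")
#'   used to identify offending entries in error messages.
#' @return `analyte_area / sis_area`.
#' @export
compute_par <- function(analyte_area, sis_area, context = NULL) {
  bad <- !is.na(sis_area) & sis_area <= 0
  if (any(bad)) {
    where <- if (!is.null(context)) {
      paste(utils::head(context[bad], 5L), collapse = "; ")
    } else {
      paste("index", paste(utils::head(which(bad), 5L), collapse = ", "))
    }
    stop("undefined peak-area ratio: SIS peak area <= 0 (", where, ")")
  }
  analyte_area / sis_area
}

#' Measured concentration from a peak area ratio
#'
#' `measured = PAR x SIS spike concentration` (fmol/uL).
#'
#' @param par non-negative peak area ratio(s).
#' @param sis_conc positive SIS spike concentration (fmol/uL).
#' @return Measured concentration(s) in fmol/uL.
#' @export
measured_concentration <- function(par, sis_conc) {
  if (!is.numeric(sis_conc) || any(is.na(sis_conc)) || any(sis_conc <= 0)) {
    stop("'sis_conc' must be a positive concentration (fmol/uL)")
  }
  par * sis_conc
}

.sis_conc_for <- function(ds, peptide) {
  sc <- ds$sis_conc
  if (length(sc) == 1L && is.null(names(sc))) return(unname(sc))
  if (!peptide %in% names(sc)) {
    stop("no SIS concentration configured for peptide ", peptide)
  }
  unname(sc[[peptide]])
}

# Pair analyte and SIS records for every key and compute measured
# concentrations. Returns one row per paired (site, study, peptide,
# transition, sample, replicate).
.measured_table <- function(ds) {
  r <- ds$records
  keep <- c("site_id", "study_phase", "protein_id", "peptide_id",
            "transition_id", "sample_id", "sample_role", "theoretical_conc",
            "replicate")
  a <- r[r$label == "analyte", c(keep, "peak_area")]
  s <- r[r$label == "SIS", c(keep, "peak_area")]
  names(a)[names(a) == "peak_area"] <- "analyte_area"
  names(s)[names(s) == "peak_area"] <- "sis_area"
  m <- merge(a, s, by = keep, sort = FALSE)
  if (nrow(m) == 0L) return(m)
  ctx <- paste(m$peptide_id, m$transition_id, m$sample_id, m$replicate,
               sep = "/")
  m$par <- compute_par(m$analyte_area, m$sis_area, context = ctx)
  sc <- vapply(m$peptide_id, function(p) .sis_conc_for(ds, p), numeric(1))
  m$measured_conc <- measured_concentration(m$par, sc)
  m
}

#' Extract calibration points for one transition
#'
#' Pairs analyte and SIS records for the requested peptide/transition,
#' computes the measured concentration of every (sample, replicate), and
#' returns the (theoretical, measured) concentration pairs used as
#' calibration-curve data.  Blanks are included with
#' `theoretical_conc = 0`.
#'
#' @param ds a `transition_dataset`.
#' @param peptide,transition identifiers selecting one monitored transition.
#' @param site,study optional filters when the dataset spans several sites or
#'   study phases.
#' @return Data frame with columns `site_id`, `study_phase`, `sample_id`,
#'   `sample_role`, `replicate`, `theoretical_conc`, `measured_conc` (both in
#'   fmol/uL), one row per paired (sample, replicate).
#' @export
calibration_points <- function(ds, peptide, transition, site = NULL,
                               study = NULL) {
  stopifnot(inherits(ds, "transition_dataset"))
  r <- ds$records
  sel <- r$peptide_id == peptide & r$transition_id == transition
  if (!is.null(site)) sel <- sel & r$site_id %in% site
  if (!is.null(study)) sel <- sel & r$study_phase %in% study
  if (!any(sel)) {
    stop("no records for peptide ", peptide, ", transition ", transition)
  }
  sub <- ds
  sub$records <- r[sel, , drop = FALSE]
  m <- .measured_table(sub)
  if (nrow(m) == 0L) {
    stop("no complete analyte/SIS pairs for peptide ", peptide,
         ", transition ", transition)
  }
  out <- m[order(m$theoretical_conc, m$sample_id, m$replicate),
           c("site_id", "study_phase", "sample_id", "sample_role",
             "replicate", "theoretical_conc", "measured_conc")]
  rownames(out) <- NULL
  out
}

#' Read an assay configuration file
#'
#' Reads a YAML key-value configuration holding e.g. `sis_conc`, a
#' `column_map`, and AuDIT/limit thresholds, as used by the command-line
#' interface.
#'
#' @param path path to a YAML file.
#' @return Named list of configuration values.
#' @export
read_assay_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$column_map)) cfg$column_map <- unlist(cfg$column_map)
  if (!is.null(cfg$sis_conc)) cfg$sis_conc <- unlist(cfg$sis_conc)
  cfg
}
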