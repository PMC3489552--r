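# Synthetic SID-MRM-MS dataset generator with known ground truth.
#
# Emulates the standard characterization design: a multi-point
# concentration curve (default nine levels, 1-500 fmol/uL) plus blanks,
# a fixed SIS spike (default 50 fmol/uL), >= 3 transitions per peptide and
# 4 replicates, with multiplicative (constant-CV) lognormal noise, an
# additive area-noise floor, and optional endogenous analyte, single-
# transition interference, detector saturation and multi-site recovery
# biases.

#' Synthetic dataset configuration
#'
#' Collects and validates the generating parameters; defaults reproduce the
#' standard characterization design described above.
#'
#' @param levels curve concentrations in fmol/uL (default the nine-point
#'   1-500 design).
#' @param sis_conc SIS spike concentration (default 50 fmol/uL, spiked into
#'   every sample including blanks).
#' @param n_replicates replicates per sample (default 4).
#' @param n_blanks number of blank samples (default 4).
#' @param n_transitions transitions per peptide (default 3).
#' @param transition_fractions relative fragment intensities, summing to 1;
#'   default proportional to `n_transitions:1`.
#' @param response_slope true recovery (slope of the measured vs theoretical
#'   line; default 1).
#' @param endogenous_conc endogenous analyte concentration in the matrix
#'   (fmol/uL; default 0).
#' @param noise_cv multiplicative noise level: the CV of replicate measured
#'   concentrations (default 0.05); implemented as lognormal noise split
#'   evenly between the analyte and SIS areas.
#' @param blank_noise_sd additive area-noise floor (area units; default
#'   125, i.e. 0.25 fmol/uL-equivalent on the strongest default
#'   transition); applied to every analyte area (blanks see its absolute
#'   value, curve points are floored at 0).
#' @param base_area area units per fmol/uL per unit transition fraction
#'   (default 1000).
#' @param interference optional `list(transition_id =, magnitude =,
#'   samples = NULL)`: additive area added to that analyte transition in the
#'   named samples (all non-blank samples when `samples` is `NULL`).
#' @param upper_saturation_level optional concentration above which analyte
#'   areas clip (detector saturation).
#' @param sites named numeric vector of per-site recovery bias multipliers
#'   (default a single unbiased site).
#' @param study_phase study phase tag for the generated records.
#' @param peptide_id,protein_id identifiers for the generated peptide.
#' @param seed optional integer seed for reproducible generation.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(levels = c(1, 2, 5, 10, 20, 50, 100, 200, 500),
                         sis_conc = 50, n_replicates = 4L, n_blanks = 4L,
                         n_transitions = 3L, transition_fractions = NULL,
                         response_slope = 1, endogenous_conc = 0,
                         noise_cv = 0.05, blank_noise_sd = 125,
                         base_area = 1000, interference = NULL,
                         upper_saturation_level = NULL, sites = NULL,
                         study_phase = "I", peptide_id = "PEP1",
                         protein_id = "PROT1", seed = NULL) {
  if (is.null(transition_fractions)) {
    transition_fractions <- rev(seq_len(n_transitions)) /
      sum(seq_len(n_transitions))
  }
  if (length(transition_fractions) != n_transitions) {
    stop("'transition_fractions' must have length n_transitions")
  }
  if (abs(sum(transition_fractions) - 1) > 1e-9) {
    stop("'transition_fractions' must sum to 1")
  }
  if (any(transition_fractions <= 0)) {
    stop("'transition_fractions' must be positive")
  }
  stopifnot(all(levels > 0), sis_conc > 0, n_replicates >= 1,
            n_blanks >= 0, n_transitions >= 1, response_slope > 0,
            endogenous_conc >= 0, noise_cv >= 0, blank_noise_sd >= 0,
            base_area > 0)
  if (is.null(sites)) sites <- c(site1 = 1)
  if (is.null(names(sites)) || any(names(sites) == "")) {
    stop("'sites' must be a named vector of bias multipliers")
  }
  if (!is.null(interference)) {
    stopifnot(is.list(interference),
              !is.null(interference$transition_id),
              is.numeric(interference$magnitude),
              interference$magnitude >= 0)
  }
  structure(list(levels = levels, sis_conc = sis_conc,
                 n_replicates = as.integer(n_replicates),
                 n_blanks = as.integer(n_blanks),
                 n_transitions = as.integer(n_transitions),
                 transition_fractions = transition_fractions,
                 response_slope = response_slope,
                 endogenous_conc = endogenous_conc, noise_cv = noise_cv,
                 blank_noise_sd = blank_noise_sd, base_area = base_area,
                 interference = interference,
                 upper_saturation_level = upper_saturation_level,
                 sites = sites, study_phase = study_phase,
                 peptide_id = peptide_id, protein_id = protein_id,
                 seed = seed),
            class = "synth_config")
}

#' Generate a synthetic transition dataset
#'
#' Simulates transition peak areas under the configured ground truth.  The
#' noise-free analyte area for transition t at spiked level x is
#' `base_area * fraction_t * site_bias * response_slope *
#' (x + endogenous_conc)`; the SIS area is the analogue at the SIS spike
#' concentration (no endogenous term, no recovery bias — the SIS is spiked
#' after the lossy steps).  Multiplicative lognormal noise with total
#' measured-concentration CV `noise_cv` is split between the two labels; an
#' additive Gaussian area floor of sd `blank_noise_sd` is superimposed on
#' every analyte area (blanks receive its absolute value).  Saturation
#' clips analyte areas at the area corresponding to
#' `upper_saturation_level`; interference adds a constant area to one
#' analyte transition in its scope.  Fully reproducible from `seed`.
#'
#' @param cfg a [synth_config()].
#' @return A [transition_dataset()] with the generating config stored in
#'   `attr(, "config")`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  # one blank sample, measured n_blanks times (its replicates), alongside
  # the curve samples measured n_replicates times each
  samples <- data.frame(
    sample_id = c(sprintf("C%02d", seq_along(cfg$levels)),
                  if (cfg$n_blanks > 0) "B01"),
    theoretical_conc = c(cfg$levels, if (cfg$n_blanks > 0) 0),
    sample_role = c(rep("curve_point", length(cfg$levels)),
                    if (cfg$n_blanks > 0) "blank"),
    stringsAsFactors = FALSE)
  trans <- sprintf("%s.t%d", cfg$peptide_id, seq_len(cfg$n_transitions))

  grid_one <- function(sample_idx, n_rep) {
    expand.grid(site_id = names(cfg$sites), sample_idx = sample_idx,
                transition_idx = seq_len(cfg$n_transitions),
                replicate = seq_len(n_rep),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  grid <- rbind(grid_one(seq_along(cfg$levels), cfg$n_replicates),
                if (cfg$n_blanks > 0)
                  grid_one(length(cfg$levels) + 1L, cfg$n_blanks))
  n <- nrow(grid)
  x <- samples$theoretical_conc[grid$sample_idx]
  role <- samples$sample_role[grid$sample_idx]
  frac <- cfg$transition_fractions[grid$transition_idx]
  bias <- cfg$sites[grid$site_id]

  # lognormal sigma per label so the PAR (measured conc) CV equals noise_cv
  sig <- sqrt(log(1 + cfg$noise_cv^2) / 2)

  a_signal <- cfg$base_area * frac * bias * cfg$response_slope *
    (x + cfg$endogenous_conc)
  a_area <- a_signal * exp(stats::rnorm(n, 0, sig))
  delta <- stats::rnorm(n, 0, cfg$blank_noise_sd)
  a_area <- ifelse(role == "blank", a_area + abs(delta),
                   pmax(a_area + delta, 0))

  s_signal <- cfg$base_area * frac * cfg$sis_conc
  s_area <- s_signal * exp(stats::rnorm(n, 0, sig))

  if (!is.null(cfg$upper_saturation_level)) {
    cap <- cfg$base_area * frac * cfg$upper_saturation_level
    a_area <- pmin(a_area, cap)
    s_area <- pmin(s_area, cap)
  }
  if (!is.null(cfg$interference)) {
    scope <- cfg$interference$samples
    if (is.null(scope)) {
      scope <- samples$sample_id[samples$sample_role != "blank"]
    }
    hit <- trans[grid$transition_idx] == cfg$interference$transition_id &
      samples$sample_id[grid$sample_idx] %in% scope
    a_area[hit] <- a_area[hit] + cfg$interference$magnitude
  }

  base_cols <- data.frame(
    site_id = grid$site_id, study_phase = cfg$study_phase,
    protein_id = cfg$protein_id, peptide_id = cfg$peptide_id,
    transition_id = trans[grid$transition_idx],
    sample_id = samples$sample_id[grid$sample_idx],
    sample_role = role, theoretical_conc = x,
    replicate = grid$replicate, stringsAsFactors = FALSE)
  records <- rbind(
    cbind(base_cols, label = "analyte", peak_area = a_area),
    cbind(base_cols, label = "SIS", peak_area = s_area))

  ds <- transition_dataset(records, sis_conc = cfg$sis_conc)
  attr(ds, "config") <- cfg
  ds
}

#' Ground-truth annotation for a synthetic dataset
#'
#' Labels every (transition, sample) cell of the generated dataset:
#' transitions receiving injected interference, in the samples within its
#' scope, are `"bad"`; everything else is `"good"`.
#'
#' @param cfg the [synth_config()] used for generation.
#' @param ds the dataset generated from `cfg`.
#' @return Data frame with columns `peptide_id`, `transition_id`,
#'   `sample_id`, `annotation`.
#' @export
truth_labels <- function(cfg, ds) {
  stopifnot(inherits(cfg, "synth_config"),
            inherits(ds, "transition_dataset"))
  r <- ds$records
  if (!all(r$peptide_id == cfg$peptide_id)) {
    stop("dataset does not match the configuration (peptide_id differs)")
  }
  cells <- unique(r[r$label == "analyte",
                    c("peptide_id", "transition_id", "sample_id")])
  cells$annotation <- "good"
  if (!is.null(cfg$interference)) {
    scope <- cfg$interference$samples
    if (is.null(scope)) {
      scope <- unique(r$sample_id[r$sample_role != "blank"])
    }
    hit <- cells$transition_id == cfg$interference$transition_id &
      cells$sample_id %in% scope
    cells$annotation[hit] <- "bad"
  }
  rownames(cells) <- NULL
  cells
}
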