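# LOD/LOQ estimators and endogenous-level detection.

test_that("blank method: 3.29 sigma with the 3xLOD / 10 sigma LOQ variants", {
  unit_sd <- vec_with_moments(4, mean = 1, sd = 1)
  fom <- lod_blank(unit_sd)
  expect_equal(fom$lod, 3.29)
  expect_equal(fom$loq, 3 * 3.29)

  expect_equal(lod_blank(c(0.2, 0.2, 0.2))$lod, 0)
  b <- c(0.1, 0.3, 0.5, 0.3)
  expect_equal(lod_blank(b)$lod, 3.29 * sd(b))
  expect_equal(lod_blank(b)$lod, 0.5373, tolerance = 1e-3)

  fom10 <- lod_blank(unit_sd, loq_rule = "10sigma")
  expect_equal(fom10$loq, 10)
  expect_error(lod_blank(c(1, 2)), "at least 3")
})

test_that("blank+low method matches the t-quantile formula", {
  blanks <- vec_with_moments(4, mean = 0.5, sd = 0.2)
  lows <- vec_with_moments(4, mean = 1, sd = 0.3)
  fom <- lod_blank_low(blanks, lows, n = 4, beta = 0.05)
  # mu_B + t(0.95, 6) * (sigma_B + sigma_S) / sqrt(4), t = 1.9432
  expect_equal(fom$lod, 0.5 + qt(0.95, 6) * 0.5 / 2, tolerance = 1e-12)
  expect_equal(fom$lod, 0.986, tolerance = 1e-3)
  expect_equal(fom$loq, 3 * fom$lod)

  # noise-free limit: lod collapses to the blank mean
  fom0 <- lod_blank_low(rep(0.5, 4), rep(1, 4))
  expect_equal(fom0$lod, 0.5)
  expect_error(lod_blank_low(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("blank and blank+low agree at the contrived consistency point", {
  # mu_B = 0, sigma_S = sigma_B, and t(1-beta, df)*2/sqrt(n) = 3.29
  beta <- 1 - pt(3.29, 6)
  blanks <- vec_with_moments(4, mean = 0, sd = 0.37)
  lows <- vec_with_moments(4, mean = 2, sd = 0.37)
  expect_equal(lod_blank_low(blanks, lows, n = 4, beta = beta)$lod,
               lod_blank(blanks)$lod, tolerance = 1e-10)
})

test_that("calibration-curve method is 3 * residual scale / slope", {
  f <- fit_calibration(line_points(x = c(1, 2, 5, 10), slope = 2),
                       "ols", ci = "none")
  expect_equal(lod_calibration_curve(f)$lod, 0)

  f$residual_scale <- 1
  fom <- lod_calibration_curve(f)
  expect_equal(fom$lod, 1.5)
  expect_equal(fom$loq, 4.5)

  f$slope <- -1
  expect_error(lod_calibration_curve(f), "slope")
})

test_that("RSD-limit method: bisection agrees with a dense grid oracle", {
  # deterministic constant-CV + floor design: observed RSD at level L is
  # exactly sqrt(0.05^2 + (0.4/L)^2)
  levels <- c(1, 2, 5, 10, 20, 50, 100, 200, 500)
  pts <- do.call(rbind, lapply(levels, function(L) {
    rsd <- sqrt(0.05^2 + (0.4 / L)^2)
    data.frame(theoretical_conc = L,
               measured_conc = vec_with_moments(4, L, rsd * L))
  }))
  fom <- loq_rsd_limit(pts, target_rsd = 0.2)
  expect_length(fom$flags, 0)
  expect_equal(fom$lod, fom$loq / 3)

  # grid oracle over the fitted model
  p1 <- fom$parameters$p1
  p2 <- fom$parameters$p2
  grid <- exp(seq(log(1), log(500), length.out = 20000))
  model <- grid * p1^(1 - p2 * log10(grid))
  oracle_loq <- grid[which(model <= 0.2)[1]]
  expect_equal(fom$loq, oracle_loq, tolerance = 1e-3)
  # the crossing lies between two adjacent design levels
  expect_gt(fom$loq, 1)
  expect_lt(fom$loq, 5)
})

test_that("RSD-limit boundary flags and minimum-design checks", {
  levels <- c(1, 2, 5, 10)
  flat <- function(r) do.call(rbind, lapply(levels, function(L) {
    data.frame(theoretical_conc = L,
               measured_conc = vec_with_moments(4, L, r * L))
  }))
  above <- loq_rsd_limit(flat(0.5), target_rsd = 0.2)
  expect_equal(above$loq, 10)
  expect_true("above_range" %in% above$flags)

  below <- loq_rsd_limit(flat(0.05), target_rsd = 0.2)
  expect_equal(below$loq, 1)
  expect_equal(below$lod, 1 / 3)
  expect_true("below_range" %in% below$flags)

  expect_error(loq_rsd_limit(flat(0.1)[1:8, ]), "at least 4")
})

test_that("endogenous estimation: exact intercepts and decision rule", {
  withp <- line_points(x = c(1, 2, 5, 10, 20, 50), intercept = 1)
  set.seed(9)
  e1 <- suppressWarnings(estimate_endogenous(withp, n_boot = 200))
  expect_true(e1$detected)
  expect_equal(e1$level, 1, tolerance = 1e-10)

  none <- line_points(x = c(1, 2, 5, 10, 20, 50))
  e0 <- suppressWarnings(estimate_endogenous(none, n_boot = 200))
  expect_false(e0$detected)
  expect_equal(e0$level, 0)

  expect_error(estimate_endogenous(withp, n_boot = 50), "at least 100")
  expect_error(estimate_endogenous(withp[1:4, ]), "at least 6")
})

test_that("endogenous-corrected LOD is the floored difference, LOQ rescaled", {
  blanks <- vec_with_moments(4, 0.5, 1.454 / 3.29)
  fom <- lod_blank(blanks)
  expect_equal(fom$lod, 1.454, tolerance = 1e-12)

  pts <- line_points(x = c(1, 2, 5, 10, 20, 50), intercept = 1.072)
  set.seed(4)
  est <- suppressWarnings(estimate_endogenous(pts, n_boot = 200))
  expect_equal(est$level, 1.072, tolerance = 1e-10)

  corr <- endogenous_corrected_lod(fom, est)
  expect_equal(corr$lod_endogenous_free, 0.382, tolerance = 1e-9)
  expect_equal(corr$loq, 3 * 0.382, tolerance = 1e-9)

  # zero endogenous level leaves the LOD unchanged
  est0 <- suppressWarnings(estimate_endogenous(
    line_points(x = c(1, 2, 5, 10, 20, 50)), n_boot = 200))
  corr0 <- endogenous_corrected_lod(fom, est0)
  expect_equal(corr0$lod_endogenous_free, fom$lod)

  # endogenous above the LOD floors at zero with a warning
  big <- line_points(x = c(1, 2, 5, 10, 20, 50), intercept = 5)
  set.seed(4)
  estb <- suppressWarnings(estimate_endogenous(big, n_boot = 200))
  expect_warning(corrb <- endogenous_corrected_lod(fom, estb), "floored")
  expect_equal(corrb$lod_endogenous_free, 0)
})

test_that("limits are invariant to replicate ordering", {
  ds <- generate_dataset(synth_config(seed = 17))
  pts <- calibration_points(ds, "PEP1", "PEP1.t1")
  perm <- pts[rev(seq_len(nrow(pts))), ]
  for (extract in list(
    function(p) lod_blank(p$measured_conc[p$sample_role == "blank"])$lod,
    function(p) lod_blank_low(p$measured_conc[p$sample_role == "blank"],
                              p$measured_conc[p$theoretical_conc == 1])$lod,
    function(p) loq_rsd_limit(p[p$sample_role != "blank", ])$lod)) {
    expect_equal(extract(perm), extract(pts), tolerance = 1e-9)
  }
})

test_that("characterize_transitions assembles the per-transition table", {
  ds <- generate_dataset(synth_config(seed = 23))
  ch <- suppressWarnings(characterize_transitions(ds, n_boot = 150))
  expect_equal(nrow(ch), 3)
  expect_true(all(ch$lod > 0))
  expect_true(all(abs(ch$slope - 1) < 0.2))
  ch_noe <- suppressWarnings(
    characterize_transitions(ds, endogenous = FALSE))
  expect_equal(ch_noe$loq, 3 * ch_noe$lod)
})
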