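# AuDIT: relative-ratio tests, p-value machinery, classification,
# evaluation.

test_that("relative ratios: cyclic minimal pairs and all-pairs counts", {
  m <- matrix(c(100, 200, 400), nrow = 1,
              dimnames = list(NULL, c("t1", "t2", "t3")))
  rs <- relative_ratios(m, "minimal_pairs")
  expect_equal(sort(unname(rs$ratios[1, ])), c(0.5, 0.5, 4))
  # each transition appears in exactly 2 pairs
  tally <- table(c(rs$pairs$numerator, rs$pairs$denominator))
  expect_true(all(tally == 2))

  m5 <- matrix(runif(20, 10, 100), nrow = 4)
  colnames(m5) <- paste0("t", 1:5)
  ap <- relative_ratios(m5, "all_pairs")
  expect_equal(nrow(ap$pairs), 10)
  tally5 <- table(c(ap$pairs$numerator, ap$pairs$denominator))
  expect_true(all(tally5 == 4))  # n - 1

  # with 2 transitions both schemes give the single pair
  m2 <- m5[, 1:2]
  expect_equal(relative_ratios(m2, "minimal_pairs")$ratios,
               relative_ratios(m2, "all_pairs")$ratios)

  m0 <- m; m0[1, 2] <- 0
  expect_error(relative_ratios(m0), "t2")
})

test_that("ratio p-values match a hand Welch oracle and handle degeneracy", {
  area_a <- cbind(t1 = c(10, 11, 9, 10), t2 = c(10, 10, 10, 10))
  area_s <- cbind(t1 = c(20, 21, 19, 20), t2 = c(10, 10, 10, 10))
  ra <- relative_ratios(area_a)
  rsx <- relative_ratios(area_s)
  pv <- ratio_pvalues(ra, rsx)
  expect_equal(pv$p_value[1],
               oracle_welch_p(area_a[, 1] / area_a[, 2],
                              area_s[, 1] / area_s[, 2]),
               tolerance = 1e-12)

  # identical ratios -> p = 1 under the equal-constant rule
  same <- relative_ratios(cbind(t1 = rep(2, 4), t2 = rep(1, 4)))
  pv1 <- ratio_pvalues(same, same)
  expect_equal(pv1$p_value, 1)
  expect_true(pv1$degenerate)

  # constant but different -> p = 0, flagged
  other <- relative_ratios(cbind(t1 = rep(4, 4), t2 = rep(1, 4)))
  pv0 <- ratio_pvalues(same, other)
  expect_equal(pv0$p_value, 0)
  expect_true(pv0$degenerate)

  # a 10-pooled-sd shift of the analyte ratios is decisively significant
  base_ratio <- c(1.0, 1.1, 0.9, 1.0)
  shift <- 10 * sd(base_ratio)
  a_shift <- relative_ratios(cbind(t1 = (base_ratio + shift) * 10,
                                   t2 = rep(10, 4)))
  s_base <- relative_ratios(cbind(t1 = base_ratio * 10, t2 = rep(10, 4)))
  pvs <- ratio_pvalues(a_shift, s_base)
  expect_equal(pvs$p_value[1],
               oracle_welch_p(base_ratio + shift, base_ratio),
               tolerance = 1e-12)
  expect_lt(pvs$p_value[1], 1e-5)
})

test_that("null ratio t-tests reject at close to the nominal rate", {
  set.seed(88)
  rej <- replicate(400, {
    a <- relative_ratios(matrix(rlnorm(8, 0, 0.05), ncol = 2,
                                dimnames = list(NULL, c("t1", "t2"))))
    s <- relative_ratios(matrix(rlnorm(8, 0, 0.05), ncol = 2,
                                dimnames = list(NULL, c("t1", "t2"))))
    ratio_pvalues(a, s)$p_value[1] < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("BH adjustment: hand example, monotonicity, domain", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(1)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("dependent p-value combination: identity, dependence collapse, monotonicity", {
  expect_equal(combine_dependent_pvalues(0.37), 0.37)
  expect_equal(combine_dependent_pvalues(c(1, 1)), 1)

  # perfect dependence collapses duplicate tests to the single test
  rho1 <- matrix(1, 2, 2)
  expect_equal(combine_dependent_pvalues(c(0.001, 0.001), rho = rho1),
               0.001, tolerance = 1e-9)
  expect_equal(combine_dependent_pvalues(c(0.2, 0.2), rho = rho1), 0.2,
               tolerance = 1e-9)

  # combining k copies never exceeds the single p: exact under perfect
  # dependence for any p; under independence Fisher's statistic gains
  # evidence for small p (the regime the classifier thresholds live in)
  for (p in c(0.001, 0.05, 0.2, 0.5, 0.9)) {
    for (k in c(2, 4)) {
      cmb <- combine_dependent_pvalues(rep(p, k), rho = matrix(1, k, k))
      expect_lte(cmb, p + 1e-9)
    }
  }
  for (p in c(0.001, 0.05, 0.2)) {
    for (k in c(2, 4)) {
      cmb <- combine_dependent_pvalues(rep(p, k), rho = diag(k))
      expect_lte(cmb, p + 1e-12)
    }
  }
  # monotone in each argument
  lo <- combine_dependent_pvalues(c(0.001, 0.3))
  hi <- combine_dependent_pvalues(c(0.01, 0.3))
  expect_lt(lo, hi)

  # alternatives stay in [0, 1] and respond to signal
  for (m in c("sidak", "stouffer")) {
    c1 <- combine_dependent_pvalues(c(0.001, 0.002), method = m)
    c2 <- combine_dependent_pvalues(c(0.6, 0.7), method = m)
    expect_lt(c1, c2)
    expect_gte(c1, 0); expect_lte(c2, 1)
  }
  expect_error(combine_dependent_pvalues(numeric(0)), "no p-values")
})

test_that("PAR CV: examples, scale invariance, guards", {
  expect_equal(par_cv(c(1, 1, 1, 1)), 0)
  expect_equal(par_cv(c(0.8, 1.0, 1.2)), 0.2)
  v <- c(0.9, 1.1, 1.4, 0.7)
  expect_equal(par_cv(17 * v), par_cv(v))
  expect_error(par_cv(c(0, 0, 0)), "mean")
  expect_error(par_cv(1), "2 replicates")
})

test_that("classification thresholds and monotonicity", {
  r1 <- classify_transitions(1e-6, 0.1)
  expect_equal(r1$flag, "bad"); expect_equal(r1$reason, "pvalue")
  r2 <- classify_transitions(0.5, 0.25)
  expect_equal(r2$flag, "bad"); expect_equal(r2$reason, "cv")
  r3 <- classify_transitions(0.5, 0.1)
  expect_equal(r3$flag, "good")

  # decreasing p or increasing cv never flips bad -> good
  set.seed(2)
  p <- runif(50); cv <- runif(50, 0, 0.4)
  base <- classify_transitions(p, cv)$flag
  harder <- classify_transitions(p / 10, cv * 1.5)$flag
  expect_false(any(base == "bad" & harder == "good"))
})

test_that("contingency metrics reproduce reference-style validation rows through the evaluator", {
  cases <- list(list(tn = 9, tp = 217, fn = 14, fp = 30, out = c(84, 94, 23)),
                list(tn = 21, tp = 162, fn = 74, fp = 13, out = c(68, 69, 62)),
                list(tn = 23, tp = 247, fn = 0, fp = 0, out = c(100, 100, 100)))
  for (cs in cases) {
    n <- cs$tn + cs$tp + cs$fn + cs$fp
    res <- data.frame(
      peptide_id = "P", sample_id = "S",
      transition_id = sprintf("t%03d", seq_len(n)),
      flag = c(rep("good", cs$tp), rep("bad", cs$tn),
               rep("good", cs$fp), rep("bad", cs$fn)),
      stringsAsFactors = FALSE)
    truth <- data.frame(
      peptide_id = "P", sample_id = "S", transition_id = res$transition_id,
      annotation = c(rep("good", cs$tp), rep("bad", cs$tn),
                     rep("bad", cs$fp), rep("good", cs$fn)),
      stringsAsFactors = FALSE)
    cm <- evaluate_against_annotation(res, truth)
    expect_equal(c(cm$accuracy_pct, cm$sensitivity_pct, cm$specificity_pct),
                 cs$out)
  }
  # unmatched keys are a join error
  res1 <- data.frame(peptide_id = "P", sample_id = "S",
                     transition_id = "tX", flag = "good")
  expect_error(evaluate_against_annotation(
    res1, data.frame(peptide_id = "P", sample_id = "S",
                     transition_id = "tY", annotation = "good")),
    "no annotation")
})

test_that("end-to-end: large injected interference is flagged, clean data is not", {
  mag <- 1000 * 0.3 * 50  # the affected transition's clean mid-curve area
  hits <- sapply(1:15, function(s) {
    cfg <- synth_config(seed = s, blank_noise_sd = 0,
                        interference = list(transition_id = "PEP1.t2",
                                            magnitude = mag))
    ds <- generate_dataset(cfg)
    a <- audit_transitions(ds)
    any(a$flag[a$transition_id == "PEP1.t2"] == "bad")
  })
  expect_true(all(hits))

  fp <- sapply(1:10, function(s) {
    a <- audit_transitions(generate_dataset(
      synth_config(seed = 500 + s, blank_noise_sd = 0)))
    mean(a$flag == "bad")
  })
  expect_lte(mean(fp), 0.05)
})

test_that("ROC sweep spans the threshold range and beats chance on interference data", {
  cfg <- synth_config(seed = 77, blank_noise_sd = 0,
                      interference = list(transition_id = "PEP1.t2",
                                          magnitude = 1000 * 0.3 * 50))
  ds <- generate_dataset(cfg)
  a <- audit_transitions(ds)
  tr <- truth_labels(cfg, ds)
  roc <- audit_roc(a, tr)
  expect_true(all(roc$table$sensitivity >= 0 & roc$table$sensitivity <= 1))
  expect_gt(roc$auc, 0.5)
})
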