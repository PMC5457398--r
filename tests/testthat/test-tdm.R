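toy_cohort <- function(benefit, progressive) {
  tibble::tibble(
    patient_id = sprintf("P%02d", seq_len(length(benefit) + length(progressive))),
    outcome = c(rep("clinical_benefit", length(benefit)),
                rep("progressive_disease", length(progressive))),
    cmin = c(benefit, progressive),
    cmax = c(benefit, progressive) * 3
  )
}

test_that("exposure summaries report sample statistics", {
  co <- toy_cohort(c(0, 40), 80)
  s <- summarize_exposure(co, "cmin")
  expect_equal(s$mean, 40)
  expect_equal(s$min, 0)
  expect_equal(s$max, 80)

  const <- toy_cohort(c(10, 10), c(10, 10))
  expect_equal(summarize_exposure(const, "cmin")$cv_pct, 0)
  expect_error(summarize_exposure(toy_cohort(5, numeric(0))[1, ], "cmin"),
               "n >= 2")
})

test_that("group comparison is a two-sided pooled-variance t-test", {
  same <- toy_cohort(c(1, 2, 3), c(1, 2, 3))
  r <- compare_groups_ttest(same, "cmin")
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)

  apart <- toy_cohort(c(101, 102, 103), c(1, 2, 3))
  expect_lt(compare_groups_ttest(apart, "cmin")$p_value, 1e-4)

  ref <- t.test(c(30, 50, 60, 45), c(10, 20, 25), var.equal = TRUE)
  ours <- compare_groups_ttest(toy_cohort(c(30, 50, 60, 45), c(10, 20, 25)),
                               "cmin")
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value)

  expect_error(compare_groups_ttest(toy_cohort(c(1, 2), 3), "cmin"),
               ">= 2 patients")
})

test_that("ROC handles perfect separation and complete overlap", {
  sep <- toy_cohort(c(50, 60, 70), c(10, 20, 30))
  r <- roc_analysis(sep, "cmin")
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity_pct, 100)
  expect_equal(r$specificity_pct, 100)
  expect_equal(r$threshold, 50)  # lowest cut achieving the maximum J

  flat <- toy_cohort(rep(42, 3), rep(42, 3))
  expect_equal(roc_analysis(flat, "cmin")$auc, 0.5)

  expect_error(roc_analysis(toy_cohort(c(1, 2, 3), numeric(0)), "cmin"),
               "both outcome classes")
})

test_that("AUC equals the Mann-Whitney statistic on tie-free data", {
  withr::with_seed(9, {
    b <- rnorm(12, 55, 15)
    p <- rnorm(8, 30, 15)
  })
  co <- toy_cohort(b, p)
  r <- roc_analysis(co, "cmin")
  u <- unname(wilcox.test(b, p)$statistic)
  expect_equal(r$auc, u / (12 * 8), tolerance = 1e-12)

  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- suppressMessages(pROC::roc(co$outcome, co$cmin,
                                      levels = c("progressive_disease",
                                                 "clinical_benefit")))
    expect_equal(r$auc, as.numeric(ref$auc), tolerance = 1e-12)
  }
})

test_that("ROC is invariant under strictly monotone exposure transforms", {
  withr::with_seed(4, co <- simulate_cohort(cohort_sim_config(seed = 4)))
  r0 <- roc_analysis(co, "cmin")
  tr <- co
  tr$cmin <- log1p(co$cmin)
  r1 <- roc_analysis(tr, "cmin")
  expect_equal(r1$auc, r0$auc)
  expect_equal(r1$sensitivity_pct, r0$sensitivity_pct)
  expect_equal(r1$specificity_pct, r0$specificity_pct)
  expect_equal(r1$threshold, log1p(r0$threshold))
})

test_that("threshold classification sends the boundary to the high group", {
  co <- toy_cohort(c(10, 33.8), 50)
  cls <- classify_threshold(co, 33.8, "cmin")
  expect_equal(cls$n_low, 1L)
  expect_equal(cls$n_high, 2L)

  all_low <- classify_threshold(toy_cohort(c(1, 2), 3), 100, "cmin")
  expect_equal(all_low$n_low, 3L)
  expect_equal(all_low$pct_low, 100)
})

test_that("exact association matches symmetry and edge expectations", {
  unit <- exact_association(matrix(1, 2, 2))
  expect_equal(unit$odds_ratio, 1, tolerance = 1e-9)
  expect_equal(unit$p_value, 1)

  diag <- exact_association(matrix(c(5, 0, 0, 5), 2, 2))
  expect_equal(diag$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(diag$odds_ratio, Inf)

  expect_error(exact_association(matrix(c(1, 0, 2, 0), 2, 2)), "margins")
  expect_error(exact_association(matrix(c(-1, 1, 1, 1), 2, 2)),
               "non-negative")
})

test_that("exact association agrees with fisher.test at its precision", {
  tables <- list(matrix(c(13, 3, 2, 7), 2, 2),
                 matrix(c(12, 4, 4, 5), 2, 2),
                 matrix(c(2, 9, 8, 1), 2, 2))
  for (m in tables) {
    ours <- exact_association(m)
    ft <- fisher.test(m)
    expect_equal(ours$p_value, ft$p.value, tolerance = 1e-12)
    # fisher.test's optimizer carries ~1e-4 relative error of its own
    expect_equal(ours$odds_ratio, unname(ft$estimate), tolerance = 1e-2)
    expect_equal(ours$ci_low, ft$conf.int[1], tolerance = 1e-2)
    expect_equal(ours$ci_high, ft$conf.int[2], tolerance = 1e-2)
  }
})

test_that("the full exposure-response wrapper ties the pieces together", {
  co <- simulate_cohort(cohort_sim_config(seed = 21))
  an <- tdm_analysis(co, "cmin")
  expect_s3_class(an$roc, "tdm_roc")
  expect_equal(sum(an$table), 25)
  expect_equal(an$classification$n_low + an$classification$n_high, 25)
  expect_equal(glance(an$roc)$threshold, an$threshold)
  expect_s3_class(autoplot(an$roc), "ggplot")
  expect_equal(nrow(tidy(an$roc)), nrow(an$roc$roc_points))
})
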