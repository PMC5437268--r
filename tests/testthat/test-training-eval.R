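test_that("ROC endpoints behave: permissive keeps all, strict rejects all", {
  ec <- eval_cohort(5, 5)
  roc <- sweep_roc(ec$cohort, ec$truth, thresholds = 0)
  expect_identical(roc$sensitivity, 1)
  roc <- sweep_roc(ec$cohort, ec$truth, thresholds = 1e9)
  expect_identical(roc$sensitivity, 0)
  expect_identical(roc$specificity, 1)
  expect_error(sweep_roc(list(), ec$truth), "empty cohort")
})

test_that("threshold selection maximizes Youden's J, ties to the smaller", {
  roc <- structure(data.frame(z_threshold = c(5, 10, 20),
                              sensitivity = c(1, 1, 1),
                              specificity = c(0.5, 0.5, 0.5),
                              youden_j = c(0.5, 0.5, 0.5)),
                   class = c("lbseq_roc", "data.frame"))
  expect_identical(select_threshold(roc), 5)
  roc$youden_j <- c(0.2, 0.9, 0.4)
  expect_identical(select_threshold(roc), 10)
  expect_identical(select_threshold(roc[2, ]), 10)
})

test_that("the vectorized sweep agrees with a per-threshold filter recount", {
  cfg <- cohort_config(n_samples = 6, n_somatic = 10, seed = 1)
  sim <- simulate_cohort(cfg)
  roc <- sweep_roc(sim$cohort, sim$truth, thresholds = c(5, 20, 50))
  for (i in seq_len(nrow(roc))) {
    cc <- suppressWarnings(concordance(
      sim$cohort, sim$truth, filter_config(z_threshold = roc$z_threshold[i])))
    expect_equal(roc$sensitivity[i], cc$sensitivity_pct / 100)
    expect_equal(roc$specificity[i], cc$specificity_pct / 100)
  }
})

test_that("sensitivity falls and specificity rises with the threshold", {
  cfg <- cohort_config(n_samples = 8, n_somatic = 12, seed = 2)
  sim <- simulate_cohort(cfg)
  roc <- sweep_roc(sim$cohort, sim$truth, thresholds = seq(1, 100, by = 3))
  expect_true(all(diff(roc$sensitivity) <= 0))
  expect_true(all(diff(roc$specificity) >= 0))
})

test_that("concordance reports rounded percent detection over cohort truth", {
  ec <- eval_cohort(27, 26)
  cc <- concordance(ec$cohort, ec$truth)
  expect_identical(cc$n_detected, 26L)
  expect_identical(cc$concordance_pct, 96L)

  ec <- eval_cohort(51, 49)
  expect_identical(concordance(ec$cohort, ec$truth)$concordance_pct, 96L)

  ec <- eval_cohort(20, 20)
  cc <- concordance(ec$cohort, ec$truth)
  expect_identical(cc$concordance_pct, 100L)
  expect_identical(cc$specificity_pct, 100)
})

test_that("cohort patients without truth records warn and count FPs only", {
  ec <- eval_cohort(3, 3)
  extra <- sample_callset("S99", rbind(calls_from_lods(seq(1, 3, length.out = 10)),
                                       calls_from_lods(500)),
                          patient_id = "P99")
  expect_warning(cc <- concordance(c(ec$cohort, list(extra)), ec$truth), "P99")
  expect_identical(cc$n_truth, 3L)
  expect_identical(nrow(cc$fp_calls), 1L)  # the kept spike of P99
  expect_lt(cc$specificity_pct, 100)
})

test_that("AF regression matches closed-form least squares", {
  # exact proportionality
  fit <- af_regression(c(0.02, 0.04, 0.08), c(0.01, 0.02, 0.04))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0)

  # hand-computed closed form for (cf, bm) pairs {(1,2),(2,3),(3,5)}
  cf <- c(1, 2, 3); bm <- c(2, 3, 5)
  sxy <- sum((cf - mean(cf)) * (bm - mean(bm)))
  fit <- af_regression(cf, bm)
  expect_equal(fit$r_squared, sxy^2 / (sum((cf - mean(cf))^2) *
                                         sum((bm - mean(bm))^2)))
  expect_equal(fit$slope, sxy / sum((bm - mean(bm))^2))
  expect_equal(fit$intercept, mean(cf) - fit$slope * mean(bm))

  expect_error(af_regression(c(1, 2), c(1, 2)), "three")
  expect_error(af_regression(c(1, 2, 3), c(1, 1, 1)), "variance")
})

test_that("subclonal rank concordance compares AF orderings", {
  # marked AF difference preserved between marrow and plasma
  res <- rank_concordance(c(0.24, 0.0072), c(0.47, 0.014))
  expect_true(res$concordant)
  expect_identical(res$verdict, "concordant")
  expect_equal(res$tau, 1)

  res <- rank_concordance(c(0.0072, 0.24), c(0.47, 0.014))
  expect_false(res$concordant)
  expect_identical(res$verdict, "discordant")

  expect_true(rank_concordance(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))$concordant)
  expect_error(rank_concordance(1:3 / 10, 1:2 / 10), "mismatch")
})

test_that("fragment-overlap phasing separates subclonal variants", {
  res <- phase_overlap(rep(c(TRUE, FALSE), c(10, 10)),
                       rep(c(FALSE, TRUE), c(10, 10)))
  expect_identical(res$shared_count, 0L)
  expect_identical(res$verdict, "mutually exclusive")

  res <- phase_overlap(rep(TRUE, 8), rep(TRUE, 8))
  expect_identical(res$verdict, "co-occurring")

  res <- phase_overlap(c(TRUE, TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE, TRUE))
  expect_identical(res$verdict, "mixed")
  expect_identical(res$shared_count, 2L)
  expect_identical(res$a_only, 1L)
  expect_identical(res$b_only, 1L)
})
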