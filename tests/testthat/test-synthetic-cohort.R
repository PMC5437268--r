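test_that("a fixed seed reproduces the cohort bit for bit", {
  cfg <- cohort_config(n_samples = 4, n_somatic = 8, seed = 11)
  sim1 <- simulate_cohort(cfg)
  sim2 <- simulate_cohort(cfg)
  expect_identical(sim1, sim2)
  # and through serialization
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(sim1, d1)
  write_cohort(sim2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("a background-free config yields exactly the requested spike", {
  cfg <- cohort_config(n_samples = 1, n_somatic = 0, seed = 5,
                       n_artefact = 0, n_germline = 0)
  set.seed(5)
  som <- cbind(panel_loci(1), af = 0.1)
  sim <- simulate_sample(cfg, 1, somatic = som)
  expect_identical(nrow(sim$callset$calls), 1L)
  expect_identical(sim$labels$label, "somatic")
  expect_equal(sim$callset$calls$tumour_f, 0.1, tolerance = 0.05)
})

test_that("labels conserve calls and the truth set lists every spike", {
  cfg <- cohort_config(n_samples = 5, n_somatic = 12, seed = 3)
  sim <- simulate_cohort(cfg)
  n_calls <- sum(vapply(sim$cohort, function(cs) nrow(cs$calls), integer(1)))
  expect_identical(nrow(sim$labels), n_calls)
  expect_true(all(sim$labels$label %in% c("artefact", "germline", "somatic")))
  expect_identical(nrow(sim$truth), 12L)
  # every emitted somatic call corresponds to a truth record of its patient
  pid <- vapply(sim$cohort, function(cs) cs$patient_id, character(1))
  names(pid) <- vapply(sim$cohort, function(cs) cs$sample_id, character(1))
  som <- sim$labels[sim$labels$label == "somatic", ]
  truth_key <- paste(sim$truth$patient_id, locus_key(sim$truth))
  expect_true(all(paste(pid[som$sample_id], som$key) %in% truth_key))
  # germline annotations are filterable by construction (default config)
  germ_af <- unlist(lapply(sim$cohort, function(cs)
    cs$calls$pop_af[!is.na(cs$calls$pop_af)]))
  expect_true(all(germ_af > 0.001))
})

test_that("observed somatic allele fractions track the binomial mean", {
  cfg <- cohort_config(n_samples = 1, n_somatic = 0, seed = 7,
                       n_artefact = 0, n_germline = 0)
  set.seed(7)
  som <- cbind(panel_loci(500), af = 0.1)
  sim <- simulate_sample(cfg, 1, somatic = som)
  af_obs <- sim$callset$calls$tumour_f
  # mean of 500 Binomial(depth ~ 20,000, 0.1) fractions: se ~ 1e-4
  se <- sqrt(0.1 * 0.9 / cfg$depth_mean / length(af_obs))
  expect_lt(abs(mean(af_obs) - 0.1), 5 * se + 0.001)
})

test_that("per-patient AF regression is exact without noise and strong with it", {
  # noiseless, unclipped: R^2 = 1 for every multi-mutation patient
  cfg0 <- cohort_config(n_samples = 6, n_somatic = 30, seed = 9,
                        bm_noise_cv = 0, bm_scale_meanlog = log(1.5),
                        bm_scale_sdlog = 0, somatic_af_range = c(0.005, 0.2))
  sim0 <- simulate_cohort(cfg0)
  af_pairs <- function(sim) {
    som <- sim$labels[sim$labels$label == "somatic", ]
    pid <- vapply(sim$cohort, function(cs) cs$patient_id, character(1))
    names(pid) <- vapply(sim$cohort, function(cs) cs$sample_id, character(1))
    truth_key <- paste(sim$truth$patient_id, locus_key(sim$truth))
    idx <- match(paste(pid[som$sample_id], som$key), truth_key)
    data.frame(patient = sim$truth$patient_id[idx],
               cf = som$true_af, bm = sim$truth$bm_af[idx])
  }
  pairs0 <- af_pairs(sim0)
  for (p in unique(pairs0$patient)) {
    sub <- pairs0[pairs0$patient == p, ]
    if (nrow(sub) >= 3) {
      expect_equal(af_regression(sub$cf, sub$bm)$r_squared, 1,
                   tolerance = 1e-9)
    }
  }

  # 5% relative BM noise: most patients stay in a high-R^2 band
  cfg <- cohort_config(n_samples = 10, n_somatic = 50, seed = 9)
  pairs <- af_pairs(simulate_cohort(cfg))
  r2 <- c()
  for (p in unique(pairs$patient)) {
    sub <- pairs[pairs$patient == p, ]
    if (nrow(sub) >= 3) {
      r2 <- c(r2, af_regression(sub$cf, sub$bm)$r_squared)
    }
  }
  expect_gte(length(r2), 5)
  expect_gte(mean(r2 >= 0.91), 0.9)
})

test_that("the training generator enforces the requested z separation", {
  cfg <- cohort_config(n_samples = 6, n_somatic = 8, seed = 13)
  sim <- simulate_training_set(cfg, separation = c(19.5, 20.5))
  for (cs in sim$cohort) {
    z <- modified_z_scores(cs)
    lab <- sim$labels$label[sim$labels$sample_id == cs$sample_id]
    expect_true(all(z[lab == "artefact"] < 19.5))
    if (any(lab == "somatic")) expect_true(all(z[lab == "somatic"] > 20.5))
  }
  # batch shifts differ between samples yet leave dispositions comparable
  batches <- vapply(sim$cohort, function(cs) cs$batch_id, character(1))
  expect_gt(length(unique(batches)), 1L)
})

test_that("a cohort survives a disk round trip with its patient mapping", {
  cfg <- cohort_config(n_samples = 3, n_somatic = 5, seed = 21)
  sim <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  back <- read_cohort(dir)
  truth <- read_truth(file.path(dir, "truth.tsv"))
  expect_identical(vapply(back, function(cs) cs$patient_id, character(1)),
                   vapply(sim$cohort, function(cs) cs$patient_id, character(1)))
  cc1 <- suppressWarnings(concordance(sim$cohort, sim$truth))
  cc2 <- suppressWarnings(concordance(back, truth))
  expect_identical(cc1$n_detected, cc2$n_detected)
  expect_identical(cc1$specificity_pct, cc2$specificity_pct)
})

test_that("an empty cohort is representable", {
  sim <- simulate_cohort(cohort_config(n_samples = 0, n_somatic = 0, seed = 1))
  expect_identical(length(sim$cohort), 0L)
  expect_identical(nrow(sim$truth), 0L)
})
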