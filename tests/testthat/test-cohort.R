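test_that("cohort defaults mirror the study conditions", {
  coh <- shared_cohort()
  expect_equal(nrow(coh$table), 57)
  expect_equal(sum(coh$modalities$modality == "radiomic"), 30)
  expect_setequal(unique(coh$table$batch), c("batch1", "batch2"))
  # Ki-67 mRNA missingness is planted near 13/57
  expect_gt(sum(is.na(coh$table$ki67_mrna)), 0)
  expect_lt(mean(is.na(coh$table$ki67_mrna)), 0.45)
})

test_that("prevalence calibration: intercept solves the marginal", {
  sp <- cohort_spec(seed = 1)
  s <- sqrt(sum(sp$effect_vector^2))
  alpha <- pcrpet:::solve_intercept(0.37, s)
  expect_equal(pcrpet:::marginal_prevalence(alpha, s), 0.37,
               tolerance = 1e-8)
  # empirical check over a large cohort
  big <- generate_cohort(cohort_spec(n_patients = 6000, seed = 3))
  expect_equal(mean(big$table$outcome == "pCR"), 0.37, tolerance = 0.03)
})

test_that("planted Bayes AUC matches a Monte-Carlo estimate", {
  sp <- cohort_spec(seed = 2)
  quad <- planted_bayes_auc(sp)
  set.seed(11)
  s <- sqrt(sum(sp$effect_vector^2))
  alpha <- pcrpet:::solve_intercept(sp$pcr_prevalence, s)
  eta <- rnorm(40000, 0, s)
  y <- rbinom(40000, 1, plogis(alpha + eta))
  mc <- suppressWarnings(as.numeric(wilcox.test(eta[y == 1],
                                                eta[y == 0])$statistic) /
                           (sum(y == 1) * sum(y == 0)))
  expect_equal(quad, mc, tolerance = 0.01)
})

test_that("scale_effect_to_auc reaches the requested Bayes AUC", {
  sp <- scale_effect_to_auc(cohort_spec(seed = 1), 0.9)
  expect_equal(planted_bayes_auc(sp), 0.9, tolerance = 1e-4)
  # direction preserved
  expect_gt(sp$effect_vector[["proliferation"]], 0)
  expect_lt(sp$effect_vector[["size"]], 0)
})

test_that("radiomic blocks carry the planted correlation structure", {
  coh <- generate_cohort(cohort_spec(n_patients = 400, seed = 5,
                                     missingness_rates = numeric(0)))
  r11 <- cor(coh$table$radiomic_c1_f1, coh$table$radiomic_c1_f3)
  r_cross <- cor(coh$table$radiomic_c1_f1, coh$table$radiomic_c2_f1)
  expect_gt(r11, 0.6)            # same cluster, same sign
  expect_lt(abs(r_cross), 0.25)  # different clusters
  # alternating sign flips within a block
  r_flip <- cor(coh$table$radiomic_c1_f1, coh$table$radiomic_c1_f2)
  expect_lt(r_flip, -0.6)
})

test_that("genomic batch shift is additive on the expression scale", {
  coh <- generate_cohort(cohort_spec(n_patients = 2000, seed = 6,
                                     missingness_rates = numeric(0)))
  b1 <- coh$table$cdc2[coh$table$batch == "batch1"]
  b2 <- coh$table$cdc2[coh$table$batch == "batch2"]
  expect_equal(mean(b2) - mean(b1), 150, tolerance = 25)
})

test_that("survival truth: planted hazard ratio raises non-pCR events", {
  coh <- generate_cohort(cohort_spec(n_patients = 4000, seed = 7))
  t1 <- coh$truth$true_event_times[coh$truth$true_labels == 1]
  t0 <- coh$truth$true_event_times[coh$truth$true_labels == 0]
  expect_equal(mean(t1) / mean(t0), 4, tolerance = 0.5)
  # censoring near the configured rate
  expect_equal(mean(coh$table$efs_event == 0), 0.7, tolerance = 0.05)
})

test_that("missingness injection is MCAR-configurable and protected", {
  coh <- shared_cohort()
  expect_error(inject_missingness(coh$table, c(outcome = 0.1)),
               "protected")
  expect_error(inject_missingness(coh$table, c(age = 1)), "rate")
  tab <- inject_missingness(coh$table, c(age = 0.5), seed = 3)
  expect_gt(sum(is.na(tab$age)), 10)
  tab2 <- inject_missingness(coh$table, c(age = 0.5), seed = 3)
  expect_identical(tab$age, tab2$age)
})

test_that("cohort generation is reproducible and seed-sensitive", {
  a <- generate_cohort(cohort_spec(seed = 8))
  b <- generate_cohort(cohort_spec(seed = 8))
  c <- generate_cohort(cohort_spec(seed = 9))
  expect_identical(a$table, b$table)
  expect_false(identical(a$table$outcome, c$table$outcome) &&
                 identical(a$table$age, c$table$age))
})

test_that("cohort CSV + sidecar round trip preserves modalities", {
  coh <- shared_cohort()
  path <- tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$modalities, coh$modalities)
  expect_equal(back$table$outcome, coh$table$outcome)
  expect_equal(back$table$mtv, coh$table$mtv, tolerance = 1e-9)
  unlink(c(path, paste0(path, ".yaml")))
})

test_that("degenerate all-zero effect vector warns", {
  expect_warning(
    generate_cohort(cohort_spec(effect_vector = c(size = 0), seed = 1)),
    "degenerate")
})
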