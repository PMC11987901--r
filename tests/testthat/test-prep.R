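test_that("encoding standardizes numerics and one-hots categoricals", {
  coh <- shared_cohort()
  fm <- encode_standardize(coh$table, coh$modalities)
  expect_s3_class(fm, "feature_matrix")
  expect_equal(mean(fm$matrix[, "age"]), 0, tolerance = 1e-12)
  expect_equal(sd(fm$matrix[, "age"]), 1, tolerance = 1e-12)
  expect_true(all(c("clinical_t_stage=T1-T2", "clinical_t_stage=T3-T4")
                  %in% colnames(fm$matrix)))
  oh <- fm$matrix[, "clinical_t_stage=T3-T4"]
  expect_true(all(oh %in% c(0, 1)))
  # meta columns never encoded
  expect_false(any(grepl("^outcome", colnames(fm$matrix))))
})

test_that("fit rows control the learned parameters (no leakage)", {
  coh <- shared_cohort()
  fit_rows <- 1:30
  fm <- encode_standardize(coh$table, coh$modalities, fit_rows = fit_rows)
  ctr <- fm$meta$center[fm$meta$column == "age"]
  expect_equal(ctr, mean(coh$table$age[fit_rows]))
  expect_equal(mean(fm$matrix[fit_rows, "age"]), 0, tolerance = 1e-12)
})

test_that("NA propagates through encoding; unseen level warns", {
  tb <- tibble::tibble(a = c(1, NA, 3, 4), b = c("x", "y", "x", "z"))
  mods <- tibble::tibble(column = c("a", "b"),
                         modality = c("clinical", "clinical"))
  expect_warning(fm <- encode_standardize(tb, mods, fit_rows = 1:3),
                 "unseen")
  expect_true(is.na(fm$matrix[2, "a"]))
  expect_equal(unname(fm$matrix[4, c("b=x", "b=y")]), c(0, 0))
})

test_that("zero-variance column passes through as zero with warning", {
  tb <- tibble::tibble(a = c(2, 2, 2), b = c(1, 2, 3))
  mods <- tibble::tibble(column = c("a", "b"), modality = "clinical")
  expect_warning(fm <- encode_standardize(tb, mods), "zero-variance")
  expect_equal(unname(fm$matrix[, "a"]), c(0, 0, 0))
})

test_that("mean-only batch correction aligns genomic batch means", {
  coh <- shared_cohort()
  fm <- encode_standardize(coh$table, coh$modalities)
  cc <- batch_correct_mean(fm, coh$table$batch)
  gcols <- cc$meta$column[cc$meta$modality == "genomic" &
                            cc$meta$encoding == "standardized"]
  for (cl in gcols) {
    m1 <- mean(cc$matrix[coh$table$batch == "batch1", cl], na.rm = TRUE)
    m2 <- mean(cc$matrix[coh$table$batch == "batch2", cl], na.rm = TRUE)
    expect_lt(abs(m1 - m2), 1e-9)
  }
  # non-genomic columns untouched
  expect_identical(cc$matrix[, "age"], fm$matrix[, "age"])
})

test_that("shrinkage pulls batch deviations toward the common mean", {
  coh <- generate_cohort(cohort_spec(n_patients = 80, seed = 4,
                                     missingness_rates = numeric(0)))
  fm <- encode_standardize(coh$table, coh$modalities)
  raw <- batch_correct_mean(fm, coh$table$batch, shrink = FALSE)
  shr <- batch_correct_mean(fm, coh$table$batch, shrink = TRUE)
  # shrinkage leaves a small residual batch-mean gap
  gcols <- fm$meta$column[fm$meta$modality == "genomic" &
                            fm$meta$encoding == "standardized"]
  gap <- function(m, cl) abs(
    mean(m[coh$table$batch == "batch1", cl], na.rm = TRUE) -
      mean(m[coh$table$batch == "batch2", cl], na.rm = TRUE))
  raw_gaps <- vapply(gcols, function(cl) gap(raw$matrix, cl), numeric(1))
  shr_gaps <- vapply(gcols, function(cl) gap(shr$matrix, cl), numeric(1))
  expect_true(all(raw_gaps < 1e-9))
  expect_true(all(shr_gaps >= 0))  # shrunk correction is not exact
})

test_that("wilcoxon and fisher wrappers agree with stats::", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value, 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(13, 14, 23, 7)$p_value,
               fisher.test(matrix(c(13, 23, 14, 7), 2))$p.value,
               tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5))$p_value, 1)
  expect_warning(res <- fisher_exact_2x2(0, 0, 3, 4), "margin")
  expect_equal(res$p_value, 1)
})

test_that("univariate screen covers every predictor with a p-value", {
  coh <- shared_cohort()
  scr <- univariate_screen(coh$table, coh$modalities)
  pred <- coh$modalities$column[coh$modalities$modality != "meta"]
  expect_setequal(scr$feature, pred)
  expect_true(all(scr$p_value >= 0 & scr$p_value <= 1, na.rm = TRUE))
  expect_true(all(grepl("^\\d\\.\\d\\d$", na.omit(scr$p_display))))
  # continuous rows summarized as median (Q1, Q3)
  age_row <- scr[scr$feature == "age", ]
  expect_match(age_row$summary_non_pcr, "^[0-9.]+ \\([0-9.]+, [0-9.]+\\)$")
})

test_that("screen matches direct tests on a spot-checked column", {
  coh <- shared_cohort()
  scr <- univariate_screen(coh$table, coh$modalities)
  y <- coh$table$outcome == "pCR"
  direct <- suppressWarnings(
    wilcox.test(coh$table$mtv[!y], coh$table$mtv[y]))$p.value
  expect_equal(scr$p_value[scr$feature == "mtv"], direct,
               tolerance = 1e-12)
  tab <- table(coh$table$clinical_t_stage, coh$table$outcome)
  expect_equal(scr$p_value[scr$feature == "clinical_t_stage"],
               fisher.test(tab)$p.value, tolerance = 1e-12)
})
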