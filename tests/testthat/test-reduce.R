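test_that("feature distance is 1 - |Spearman| with zero diagonal", {
  set.seed(1)
  x <- matrix(rnorm(200), 50, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  x[, 2] <- -x[, 1]  # perfect negative monotone
  d <- as.matrix(pcrpet:::feature_distance(x))
  expect_equal(unname(d["f1", "f2"]), 0, tolerance = 1e-12)
  expect_equal(unname(diag(d)), rep(0, 4))
  rho <- cor(x[, 3], x[, 4], method = "spearman")
  expect_equal(unname(d["f3", "f4"]), 1 - abs(rho), tolerance = 1e-12)
})

test_that("constant feature is maximally distant with a warning", {
  x <- cbind(a = rnorm(20), b = rep(1, 20), c = rnorm(20))
  expect_warning(d <- pcrpet:::feature_distance(x), "constant")
  expect_equal(unname(as.matrix(d)["a", "b"]), 1)
})

test_that("stability clustering recovers the planted radiomic blocks", {
  coh <- generate_cohort(cohort_spec(n_patients = 120, seed = 2,
                                     missingness_rates = numeric(0)))
  rad <- as.matrix(coh$table[, names(coh$truth$cluster_assignment)])
  sol <- cluster_radiomics(rad, k_range = 2:10, n_boot = 30, seed = 1)
  expect_equal(sol$k, 6)
  ari <- mclust::adjustedRandIndex(
    sol$assignment[names(coh$truth$cluster_assignment)],
    coh$truth$cluster_assignment)
  expect_gt(ari, 0.99)
  expect_equal(length(sol$representatives), 6)
})

test_that("clustering is reproducible by seed", {
  coh <- shared_cohort()
  rad <- as.matrix(coh$table[, names(coh$truth$cluster_assignment)])
  a <- cluster_radiomics(rad, k_range = 2:8, n_boot = 20, seed = 5)
  b <- cluster_radiomics(rad, k_range = 2:8, n_boot = 20, seed = 5)
  expect_identical(a$assignment, b$assignment)
  expect_identical(a$stability_profile, b$stability_profile)
})

test_that("representatives are in-cluster correlation hubs", {
  coh <- generate_cohort(cohort_spec(n_patients = 150, seed = 3,
                                     missingness_rates = numeric(0)))
  rad <- as.matrix(coh$table[, names(coh$truth$cluster_assignment)])
  sol <- cluster_radiomics(rad, k_range = 2:8, n_boot = 20, seed = 1)
  for (g in unique(sol$assignment)) {
    members <- names(sol$assignment)[sol$assignment == g]
    rep_name <- sol$representatives[[as.character(g)]]
    expect_true(rep_name %in% members)
  }
})

test_that("missingness filter drops only heavy-missing predictors", {
  tb <- tibble::tibble(patient_id = as.character(1:10),
                       outcome = rep(c("pCR", "non-pCR"), 5),
                       good = rnorm(10),
                       bad = c(rnorm(4), rep(NA, 6)))
  res <- filter_by_missingness(tb, threshold = 0.5)
  expect_true("good" %in% res$retained)
  expect_equal(res$dropped, "bad")
  expect_true(all(c("patient_id", "outcome") %in% res$retained))
  # threshold is inclusive on the drop side
  res2 <- filter_by_missingness(tb, threshold = 0.61)
  expect_length(res2$dropped, 0)
})

test_that("MICE imputation fills all missing values deterministically", {
  set.seed(4)
  n <- 80
  z <- rnorm(n)
  df <- tibble::tibble(a = z + rnorm(n, sd = 0.3),
                       b = -z + rnorm(n, sd = 0.3),
                       c = sample(c("u", "v"), n, replace = TRUE))
  df$a[sample(n, 15)] <- NA
  df$c[sample(n, 8)] <- NA
  out1 <- mice_impute(df, n_iter = 3, seed = 7)
  out2 <- mice_impute(df, n_iter = 3, seed = 7)
  expect_false(anyNA(out1))
  expect_identical(out1, out2)
  expect_identical(out1$b, df$b)  # observed values untouched
  expect_type(out1$c, "character")
})

test_that("MICE exploits correlation better than median fill", {
  set.seed(9)
  n <- 120
  z <- rnorm(n)
  truth <- z + rnorm(n, sd = 0.2)
  df <- data.frame(a = truth, b = z + rnorm(n, sd = 0.2),
                   c = z + rnorm(n, sd = 0.2))
  miss <- sample(n, 30)
  df$a[miss] <- NA
  filled <- mice_impute(df, n_iter = 5, seed = 1)
  rmse_mice <- sqrt(mean((filled$a[miss] - truth[miss])^2))
  rmse_med <- sqrt(mean((median(df$a, na.rm = TRUE) - truth[miss])^2))
  expect_lt(rmse_mice, rmse_med)
})

test_that("fully missing column errors", {
  df <- data.frame(a = c(NA_real_, NA_real_), b = c(1, 2))
  expect_error(mice_impute(df), "no observed values")
})

test_that("select_features combines include-list and representatives", {
  coh <- shared_cohort()
  rad <- as.matrix(coh$table[, names(coh$truth$cluster_assignment)])
  sol <- cluster_radiomics(rad, k_range = 2:8, n_boot = 20, seed = 1)
  sel <- select_features(coh$table, coh$modalities, sol)
  expect_s3_class(sel, "selected_features")
  expect_true(all(unname(sol$representatives) %in% sel$feature))
  expect_true("ggir" %in% sel$feature)
  expect_true(all(c("feature", "modality") %in% names(sel)))
  expect_equal(nrow(sel), length(unique(sel$feature)))
})
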