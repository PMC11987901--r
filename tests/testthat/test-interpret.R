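test_that("linear coefficients are ranked by absolute weight", {
  set.seed(1)
  n <- 300
  x <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rbinom(n, 1, plogis(2 * x[, 3]))
  fin <- final_model(x, y, model_spec("linear-svm", grid = list(cost = 1)),
                     seed = 1, lpocv = FALSE)
  rk <- linear_coefficients(fin)
  expect_equal(rk$feature[1], "f3")
  expect_gt(rk$weight[1], 0)
  expect_true(all(diff(rk$abs_weight) <= 0))
  expect_equal(rk$rank, seq_len(nrow(rk)))
})

test_that("planted informative feature ranks first across seeds", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 500
    x <- matrix(rnorm(n * 10), n,
                dimnames = list(NULL, paste0("f", 1:10)))
    y <- rbinom(n, 1, plogis(2 * x[, 1]))
    fin <- final_model(x, y,
                       model_spec("logistic-ridge",
                                  grid = list(lambda = 0.01)),
                       seed = s, lpocv = FALSE)
    if (linear_coefficients(fin)$feature[1] == "f1") hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("non-linear family errors with a pointer to SHAP", {
  set.seed(2)
  x <- matrix(rnorm(60), 30, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(30, 1, 0.5); y[1] <- 1; y[2] <- 0
  fin <- final_model(x, y, model_spec("decision-tree",
                                      grid = list(maxdepth = 2)),
                     seed = 1, lpocv = FALSE)
  expect_error(linear_coefficients(fin), "SHAP")
})

test_that("modality tags are joined onto the ranking", {
  coh <- shared_cohort()
  fm <- encode_standardize(coh$table, coh$modalities)
  keep <- c("age", "mtv", "ggir", "clinical_t_stage=T3-T4")
  x <- fm$matrix[, keep]
  fin <- final_model(x, coh$table$outcome,
                     model_spec("linear-svm", grid = list(cost = 1)),
                     seed = 1, lpocv = FALSE)
  rk <- linear_coefficients(fin, coh$modalities)
  expect_equal(rk$modality[rk$feature == "ggir"], "genomic")
  expect_equal(rk$modality[rk$feature == "clinical_t_stage=T3-T4"],
               "clinical")
})

test_that("SHAP: identity at baseline, exact additivity, zero weights", {
  set.seed(3)
  n <- 100
  x <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(n, 1, plogis(x[, 1]))
  fin <- final_model(x, y, model_spec("linear-svm", grid = list(cost = 1)),
                     seed = 1, lpocv = FALSE)
  base <- colMeans(x)
  at_base <- linear_shap(fin, base)
  expect_equal(max(abs(at_base$contributions)), 0, tolerance = 1e-12)
  sh <- linear_shap(fin, x)
  err <- abs(sh$base_value + rowSums(sh$contributions) - sh$margin)
  expect_lt(max(err), 1e-9)
  # contribution of feature i is w_i (x_i - baseline_i), non-pCR oriented
  w <- fin$coefficients
  expect_equal(sh$contributions[, 2], -w[2] * (x[, 2] - base[2]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("zero-weight feature contributes nothing", {
  set.seed(4)
  x <- matrix(rnorm(400), 100, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(100, 1, plogis(3 * x[, 1]))
  fin <- final_model(x, y, model_spec("logistic-lasso",
                                      grid = list(lambda = 0.2)),
                     seed = 1, lpocv = FALSE)
  w <- fin$coefficients
  zero <- which(w == 0)
  expect_gt(length(zero), 0)  # lasso at this penalty drops noise
  sh <- linear_shap(fin, x)
  expect_equal(max(abs(sh$contributions[, zero])), 0)
})

test_that("baseline length mismatch errors", {
  set.seed(5)
  x <- matrix(rnorm(60), 30, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(30, 1, 0.5); y[1] <- 1; y[2] <- 0
  fin <- final_model(x, y, model_spec("linear-svm", grid = list(cost = 1)),
                     seed = 1, lpocv = FALSE)
  expect_error(linear_shap(fin, x, baseline = c(0, 0, 0)), "length")
})
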