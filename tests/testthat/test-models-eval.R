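test_that("discordant pair enumeration has the right count and order", {
  labs <- rep(c("pCR", "non-pCR"), c(21, 36))
  pr <- enumerate_discordant_pairs(labs)
  expect_equal(nrow(pr), 756)
  expect_equal(nrow(dplyr::distinct(pr)), 756)
  expect_equal(nrow(enumerate_discordant_pairs(c("pCR", "non-pCR"))), 1)
  expect_equal(nrow(enumerate_discordant_pairs(
    rep(c(1, 0), c(3, 4)))), 12)
  expect_error(enumerate_discordant_pairs(rep("pCR", 5)), "both")
})

test_that("lpo_auc: perfect, tied and oracle-checked scores", {
  expect_equal(lpo_auc(tibble::tibble(pos_score = c(2, 3),
                                      neg_score = c(1, 0))), 1)
  expect_equal(lpo_auc(tibble::tibble(pos_score = rep(1, 5),
                                      neg_score = rep(1, 5))), 0.5)
  set.seed(3)
  for (i in 1:20) {
    pos <- round(rnorm(7), 1); neg <- round(rnorm(9), 1)
    pr <- tidyr::expand_grid(pos_score = pos, neg_score = neg)
    expect_equal(lpo_auc(pr), oracle_mann_whitney(pos, neg))
  }
})

test_that("each model family fits, scores in orientation, reproduces", {
  set.seed(5)
  n <- 60
  x <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("f", 1:4)))
  y_num <- rbinom(n, 1, plogis(2 * x[, 1]))
  y <- factor(ifelse(y_num == 1, "pCR", "non-pCR"),
              levels = c("non-pCR", "pCR"))
  for (fam in c("linear-svm", "logistic-lasso", "logistic-ridge",
                "logistic-elasticnet", "decision-tree",
                "random-forest")) {
    spec <- model_spec(fam)
    hyper <- spec$grid[1, , drop = FALSE]
    fit <- pcrpet:::fit_one(fam, x, y, hyper, seed = 1)
    sc <- pcrpet:::score_one(fam, fit, x)
    expect_length(sc, n)
    # scores must rank pCR above non-pCR on separable-ish data
    expect_gt(mean(sc[y == "pCR"]), mean(sc[y == "non-pCR"]))
    fit2 <- pcrpet:::fit_one(fam, x, y, hyper, seed = 1)
    expect_equal(pcrpet:::score_one(fam, fit2, x), sc)
  }
})

test_that("model_spec validates family and builds the grid", {
  expect_error(model_spec("boosted-trees"), "arg")
  sp <- model_spec("logistic-elasticnet")
  expect_equal(nrow(sp$grid), 12)  # 4 lambda x 3 alpha
  expect_s3_class(sp, "model_spec")
})

test_that("inner_select returns a single-point grid unchanged", {
  sp <- model_spec("linear-svm", grid = list(cost = 2.5))
  x <- matrix(rnorm(40), 20)
  y <- rep(c("pCR", "non-pCR"), 10)
  sel <- inner_select(x, y, sp, seed = 1)
  expect_equal(sel$hyper$cost, 2.5)
})

test_that("inner_select picks a sensible point on separable data", {
  set.seed(8)
  n <- 40
  x <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("f", 1:3)))
  y <- ifelse(x[, 1] > 0, "pCR", "non-pCR")
  x[, 1] <- x[, 1] + sign(x[, 1]) * 2  # widen the margin
  sp <- model_spec("linear-svm")
  sel <- inner_select(x, y, sp, n_inner_pairs = 30, seed = 2)
  expect_equal(sel$inner_auc, 1)
  # perfect tie across all grid points -> canonical first row
  expect_equal(sel$hyper, sp$grid[1, , drop = FALSE])
  sel2 <- inner_select(x, y, sp, n_inner_pairs = 30, seed = 2)
  expect_identical(sel$grid_auc, sel2$grid_auc)
})

test_that("nested LPOCV: bookkeeping, report invariants, determinism", {
  coh <- shared_cohort()
  sp <- model_spec("logistic-ridge", grid = list(lambda = 0.5))
  rep <- nested_lpocv(coh$table, coh$modalities, sp, modality_set = 1,
                      seed = 3)
  y <- coh$table$outcome
  expect_equal(nrow(rep$pair_scores),
               sum(y == "pCR") * sum(y == "non-pCR"))
  expect_gte(rep$auc, 0); expect_lte(rep$auc, 1)
  expect_true(all(rep$per_patient$probability >= 0 &
                    rep$per_patient$probability <= 1))
  expect_equal(rep$mode, "paper")
  # metrics recomputable from the per-patient table
  m <- pcrpet:::classification_metrics(
    factor(rep$per_patient$outcome, levels = c("non-pCR", "pCR")),
    rep$per_patient$probability)
  expect_equal(rep$metrics, m)
  rep2 <- nested_lpocv(coh$table, coh$modalities, sp, modality_set = 1,
                       seed = 3)
  expect_equal(rep$pair_scores, rep2$pair_scores)
})

test_that("strict mode refits the transform per fold and is flagged", {
  coh <- shared_cohort()
  sp <- model_spec("logistic-ridge", grid = list(lambda = 0.5))
  rep <- nested_lpocv(coh$table, coh$modalities, sp,
                      modality_set = c("age", "mtv", "tumor_suvmax"),
                      mode = "strict", seed = 4)
  expect_equal(rep$mode, "strict")
  expect_gte(rep$auc, 0); expect_lte(rep$auc, 1)
})

test_that("zero-column modality set errors", {
  coh <- shared_cohort()
  sp <- model_spec("linear-svm", grid = list(cost = 1))
  expect_error(nested_lpocv(coh$table, coh$modalities, sp,
                            modality_set = "no_such_column", seed = 1),
               "zero columns")
})

test_that("bootstrap: degenerate all-correct scores give CI [1, 1]", {
  labs <- rep(c("pCR", "non-pCR"), c(4, 5))
  pr <- enumerate_discordant_pairs(labs)
  rep <- list(pair_scores = dplyr::mutate(pr, pos_score = 2,
                                          neg_score = 1))
  bs <- bootstrap_pairs(rep, n_boot = 500, seed = 1)
  expect_equal(bs$auc, 1)
  expect_equal(bs$ci_lower, 1)
  expect_equal(bs$ci_upper, 1)
})

test_that("bootstrap self-comparison gives the floored p = 1 scale", {
  coh <- shared_cohort()
  sp <- model_spec("logistic-ridge", grid = list(lambda = 0.5))
  rep <- nested_lpocv(coh$table, coh$modalities, sp, modality_set = 1,
                      seed = 3)
  bs <- bootstrap_pairs(rep, rep, n_boot = 400, seed = 2)
  expect_equal(bs$diff, 0)
  expect_equal(bs$p_value, 1)
  expect_warning(bootstrap_pairs(rep, n_boot = 50, seed = 1),
                 "n_boot")
})

test_that("bootstrap CI brackets the point AUC and is reproducible", {
  coh <- shared_cohort()
  sp <- model_spec("logistic-ridge", grid = list(lambda = 0.5))
  rep <- nested_lpocv(coh$table, coh$modalities, sp, modality_set = 1,
                      seed = 3)
  b1 <- bootstrap_pairs(rep, n_boot = 500, seed = 9)
  b2 <- bootstrap_pairs(rep, n_boot = 500, seed = 9)
  expect_identical(b1$replicates, b2$replicates)
  expect_lte(b1$ci_lower, rep$auc)
  expect_gte(b1$ci_upper, rep$auc)
  expect_gte(b1$ci_lower, 0); expect_lte(b1$ci_upper, 1)
})

test_that("final model recovers planted coefficient signs", {
  ok <- 0
  for (s in 1:5) {
    set.seed(s)
    n <- 200
    x <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
    y <- rbinom(n, 1, plogis(1.5 * x[, 1] - 1.5 * x[, 2]))
    fin <- final_model(x, y, model_spec("linear-svm",
                                        grid = list(cost = 1)),
                       seed = s, lpocv = FALSE)
    w <- fin$coefficients
    if (w[1] > 0 && w[2] < 0) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("final model per-patient probabilities and determinism", {
  set.seed(10)
  x <- matrix(rnorm(40 * 3), 40, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rbinom(40, 1, 0.4)
  if (sum(y) == 0) y[1] <- 1
  fin <- final_model(x, y, model_spec("random-forest",
                                      grid = list(mtry_frac = NA,
                                                  num_trees = 100)),
                     seed = 4)
  expect_true(all(fin$per_patient$probability >= 0 &
                    fin$per_patient$probability <= 1))
  fin2 <- final_model(x, y, model_spec("random-forest",
                                       grid = list(mtry_frac = NA,
                                                   num_trees = 100)),
                      seed = 4)
  expect_equal(fin$per_patient$probability, fin2$per_patient$probability)
})

test_that("glance/tidy methods summarize reports", {
  coh <- shared_cohort()
  sp <- model_spec("logistic-ridge", grid = list(lambda = 0.5))
  rep <- nested_lpocv(coh$table, coh$modalities, sp, modality_set = 1,
                      seed = 3)
  g <- generics::glance(rep)
  expect_equal(nrow(g), 1)
  expect_equal(g$auc, rep$auc)
  t <- generics::tidy(rep)
  expect_equal(mean(t$correct), rep$auc)
})
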