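#' Specify a model family and its hyperparameter grid
#'
#' The model zoo covers regularized logistic regression (LASSO, Ridge,
#' Elastic-net), binary decision trees, linear-kernel support vector
#' machines and random forests. Default grids are small, standard and
#' fully configurable.
#'
#' @param family One of `"linear-svm"`, `"logistic-lasso"`,
#'   `"logistic-ridge"`, `"logistic-elasticnet"`, `"decision-tree"`,
#'   `"random-forest"`.
#' @param grid Named list of hyperparameter vectors; crossed into a grid
#'   whose row order (first = canonical tie-break winner) follows
#'   `expand.grid`.
#' @param seed Integer seed for randomized families.
#' @return A `model_spec`.
#' @export
#' @examples
#' model_spec("linear-svm", grid = list(cost = c(0.1, 1)))
model_spec <- function(family = c("linear-svm", "logistic-lasso",
                                  "logistic-ridge", "logistic-elasticnet",
                                  "decision-tree", "random-forest"),
                       grid = NULL, seed = 1L) {
  family <- match.arg(family)
  if (is.null(grid)) grid <- default_grid(family)
  assert_that(length(grid) > 0 && nrow(expand.grid(grid)) > 0,
              "hyperparameter grid must be nonempty")
  structure(
    list(family = family,
         grid = expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE),
         seed = as.integer(seed)),
    class = "model_spec"
  )
}

default_grid <- function(family) {
  switch(family,
    "linear-svm" = list(cost = c(0.01, 0.1, 1, 10)),
    "logistic-lasso" = list(lambda = c(0.01, 0.1, 1, 10)),
    "logistic-ridge" = list(lambda = c(0.01, 0.1, 1, 10)),
    "logistic-elasticnet" = list(lambda = c(0.01, 0.1, 1, 10),
                                 alpha = c(0.25, 0.5, 0.75)),
    "decision-tree" = list(maxdepth = c(2, 3, 4, 5)),
    "random-forest" = list(mtry_frac = c(NA, 1 / 3), num_trees = 500)
  )
}

# fit one model; y is a factor with levels c("non-pCR", "pCR")
fit_one <- function(family, x, y, hyper, seed = 1L) {
  switch(family,
    "linear-svm" = e1071::svm(x, y, kernel = "linear",
                              cost = hyper$cost, scale = FALSE),
    "logistic-lasso" = glmnet::glmnet(x, y, family = "binomial",
                                      alpha = 1, lambda = hyper$lambda),
    "logistic-ridge" = glmnet::glmnet(x, y, family = "binomial",
                                      alpha = 0, lambda = hyper$lambda),
    "logistic-elasticnet" = glmnet::glmnet(x, y, family = "binomial",
                                           alpha = hyper$alpha,
                                           lambda = hyper$lambda),
    "decision-tree" = {
      df <- as.data.frame(x); df$.y <- y
      rpart::rpart(.y ~ ., df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = hyper$maxdepth, cp = 0.001,
                     minsplit = 5, xval = 0))
    },
    "random-forest" = {
      mtry <- if (is.na(hyper$mtry_frac)) floor(sqrt(ncol(x))) else
        max(1, floor(ncol(x) * hyper$mtry_frac))
      ranger::ranger(x = as.data.frame(x), y = y, probability = TRUE,
                     num.trees = hyper$num_trees, mtry = mtry,
                     seed = seed, num.threads = 1)
    },
    abort(paste("unknown family:", family))
  )
}

# score new rows: decision margin for svm, P(pCR) otherwise;
# higher always means more pCR-like
score_one <- function(family, model, newx) {
  switch(family,
    "linear-svm" = {
      pr <- predict(model, newx, decision.values = TRUE)
      dv <- drop(attr(pr, "decision.values"))
      lab <- colnames(attr(pr, "decision.values"))[1]
      # positive decision values favor the first label of "a/b"
      first <- strsplit(lab, "/", fixed = TRUE)[[1]][1]
      if (first == "pCR") dv else -dv
    },
    "decision-tree" = {
      unname(predict(model, as.data.frame(newx), type = "prob")[, "pCR"])
    },
    "random-forest" = {
      unname(predict(model, as.data.frame(newx),
                     num.threads = 1)$predictions[, "pCR"])
    },
    # glmnet families
    unname(drop(predict(model, newx, type = "response")))
  )
}

# linear coefficient vector on the standardized feature scale (NULL for
# non-linear families)
coef_one <- function(family, model, feature_names) {
  if (family == "linear-svm") {
    w <- drop(crossprod(model$coefs, model$SV))
    # e1071's decision value is positive for its internal first class,
    # which is order-of-appearance (model$labels), not factor level
    # order; orient so positive weights push toward pCR
    first <- model$levels[model$labels[1]]
    if (first == "pCR") w else -w
  } else if (startsWith(family, "logistic")) {
    drop(coef(model))[-1]
  } else NULL
}
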