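#' Ranked coefficients of a linear model
#'
#' Returns the signed weights of a linear-family [final_model()] on the
#' standardized feature scale, sorted by absolute value, with the
#' modality of each feature. Positive weights push the prediction
#' toward pCR.
#'
#' @param model A `final_model` with a linear family (linear-svm or a
#'   logistic variant).
#' @param modalities Optional column-to-modality tibble; encoded
#'   one-hot columns are matched through their source column.
#' @return A `coefficient_ranking` tibble: `feature`, `weight`,
#'   `abs_weight`, `rank`, `modality`.
#' @export
linear_coefficients <- function(model, modalities = NULL) {
  stopifnot(inherits(model, "final_model"))
  w <- model$coefficients
  if (is.null(w))
    abort(paste0("`", model$family, "` has no linear coefficients; ",
                 "use SHAP-style attributions for non-linear families"))
  out <- tibble(feature = model$feature_names, weight = unname(w)) |>
    filter(.data$weight != 0) |>
    mutate(abs_weight = abs(.data$weight)) |>
    arrange(dplyr::desc(.data$abs_weight)) |>
    mutate(rank = dplyr::row_number())
  if (!is.null(modalities)) {
    src <- sub("=.*$", "", out$feature)
    out$modality <- modalities$modality[match(src, modalities$column)]
  }
  class(out) <- c("coefficient_ranking", class(out))
  out
}

#' Exact Shapley attributions for a linear model
#'
#' For a linear model with the independent-feature value function the
#' Shapley value of feature i is exactly `w_i * (x_i - baseline_i)`.
#' The base value is the margin at the baseline point, and base value
#' plus the sum of contributions equals the predicted margin exactly.
#' Positive contributions push toward non-pCR, the explained class.
#'
#' @param model A linear-family `final_model`.
#' @param x Numeric matrix (or single row) of fully observed,
#'   prepared feature values to explain.
#' @param baseline Baseline feature vector (default: the training
#'   mean stored in the model).
#' @return A `shap_attribution`: `contributions` matrix (patients x
#'   features, non-pCR orientation), `base_value`, `margin` per patient.
#' @export
#' @examples
#' # x == baseline gives all-zero contributions
linear_shap <- function(model, x, baseline = NULL) {
  stopifnot(inherits(model, "final_model"))
  w <- model$coefficients
  if (is.null(w))
    abort("SHAP closed form requires a linear family")
  if (is.null(dim(x))) x <- matrix(x, 1, dimnames = list(NULL, names(x)))
  assert_that(ncol(x) == length(w), "x has wrong number of features")
  if (is.null(baseline)) baseline <- model$training_mean
  assert_that(length(baseline) == length(w),
              "`baseline` length must match the feature count")
  # w is oriented toward pCR; the explained class is non-pCR
  contrib <- sweep(x, 2, baseline) %*% diag(-unname(w), length(w))
  colnames(contrib) <- model$feature_names
  base <- sum(-unname(w) * baseline)
  structure(
    list(contributions = contrib, base_value = base,
         margin = base + rowSums(contrib),
         explained_class = "non-pCR"),
    class = "shap_attribution")
}

#' @export
print.shap_attribution <- function(x, ...) {
  cat("<shap_attribution> ", nrow(x$contributions), " patient(s) x ",
      ncol(x$contributions), " features; explained class: ",
      x$explained_class, "\n", sep = "")
  invisible(x)
}
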