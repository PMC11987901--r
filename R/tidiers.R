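#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy an evaluation report into one row per outer pair
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble of pair-level held-out scores.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  x$pair_scores |>
    mutate(correct = (.data$pos_score > .data$neg_score) +
             0.5 * (.data$pos_score == .data$neg_score))
}

#' One-row summary of an evaluation report
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One-row tibble: family, modality set, mode, AUC, confusion
#'   metrics.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble(family = x$family, modality_set = x$modality_set,
           mode = x$mode, n_pairs = nrow(x$pair_scores), auc = x$auc),
    x$metrics)
}

#' Tidy a bootstrap result into one row per replicate
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @return Tibble with `replicate`, `auc` (and `diff` for comparisons).
#' @method tidy bootstrap_result
#' @export
tidy.bootstrap_result <- function(x, ...) {
  out <- tibble(replicate = seq_along(x$replicates), auc = x$replicates)
  if (!is.null(x$diff_replicates)) out$diff <- x$diff_replicates
  out
}

#' One-row summary of a bootstrap result
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @return One-row tibble with the point AUC, CI and (for
#'   comparisons) the difference and p-value.
#' @method glance bootstrap_result
#' @export
glance.bootstrap_result <- function(x, ...) {
  out <- tibble(auc = x$auc, ci_lower = x$ci_lower,
                ci_upper = x$ci_upper, n_boot = x$n_boot)
  if (!is.null(x$p_value)) {
    out$auc_b <- x$auc_b; out$diff <- x$diff; out$p_value <- x$p_value
  }
  out
}

#' Tidy a final model into one row per nonzero coefficient
#' @param x A `final_model`.
#' @param ... Unused.
#' @return Coefficient tibble (linear families) via
#'   [linear_coefficients()].
#' @method tidy final_model
#' @export
tidy.final_model <- function(x, ...) {
  linear_coefficients(x)
}

#' One-row summary of a final model
#' @param x A `final_model`.
#' @param ... Unused.
#' @return One-row tibble: family, feature count, LPOCV AUC.
#' @method glance final_model
#' @export
glance.final_model <- function(x, ...) {
  tibble(family = x$family, n_features = length(x$feature_names),
         auc = x$auc)
}

#' Tidy a cluster solution into one row per feature
#' @param x A `cluster_solution`.
#' @param ... Unused.
#' @return Tibble: feature, cluster, representative flag.
#' @method tidy cluster_solution
#' @export
tidy.cluster_solution <- function(x, ...) {
  tibble(feature = names(x$assignment),
         cluster = unname(x$assignment)) |>
    mutate(representative = .data$feature %in% x$representatives)
}

#' One-row summary of a cluster solution
#' @param x A `cluster_solution`.
#' @param ... Unused.
#' @return One-row tibble: chosen k, features, peak stability.
#' @method glance cluster_solution
#' @export
glance.cluster_solution <- function(x, ...) {
  tibble(k = x$k, n_features = length(x$assignment),
         stability = max(x$stability_profile$stability))
}
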