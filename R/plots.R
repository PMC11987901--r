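#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_point geom_col
#'   geom_errorbar geom_hline labs theme_minimal facet_wrap coord_flip
NULL

#' Plot a Kaplan-Meier estimate
#'
#' Step curves per group with censoring ticks.
#'
#' @param object A [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot km_estimate
#' @export
autoplot.km_estimate <- function(object, ...) {
  # prepend the (0, 1) anchor so every curve starts at full survival
  anchors <- object |>
    dplyr::distinct(.data$group) |>
    mutate(time = 0, survival = 1, n_censor = 0L)
  dat <- dplyr::bind_rows(anchors, object) |>
    arrange(.data$group, .data$time)
  p <- ggplot(dat, aes(x = .data$time, y = .data$survival,
                       color = .data$group)) +
    geom_step() +
    geom_point(data = dplyr::filter(dat, .data$n_censor > 0),
               shape = 3) +
    labs(x = "Time (months)", y = "Event-free survival",
         color = NULL) +
    ggplot2::ylim(0, 1) +
    theme_minimal()
  p
}

#' Plot ranked linear-model coefficients
#'
#' Horizontal bars sorted by absolute weight, colored by modality when
#' available; positive weights push toward pCR.
#'
#' @param object A [linear_coefficients()] ranking.
#' @param top_n Show at most this many features.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coefficient_ranking
#' @export
autoplot.coefficient_ranking <- function(object, top_n = 20, ...) {
  dat <- object |>
    dplyr::slice_head(n = top_n) |>
    mutate(feature = factor(.data$feature,
                            levels = rev(.data$feature)))
  map_color <- "modality" %in% names(dat)
  p <- ggplot(dat, aes(x = .data$feature, y = .data$weight)) +
    (if (map_color) geom_col(aes(fill = .data$modality)) else geom_col()) +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    coord_flip() +
    labs(x = NULL, y = "Weight (standardized scale, + = pCR)",
         fill = NULL) +
    theme_minimal()
  p
}

#' Plot the cluster-stability profile
#'
#' Mean adjusted Rand index versus candidate cluster count, with the
#' chosen k marked.
#'
#' @param object A [cluster_radiomics()] solution.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cluster_solution
#' @export
autoplot.cluster_solution <- function(object, ...) {
  ggplot(object$stability_profile,
         aes(x = .data$k, y = .data$stability)) +
    ggplot2::geom_line() +
    geom_point() +
    geom_point(data = dplyr::filter(object$stability_profile,
                                    .data$k == object$k),
               color = "red", size = 3) +
    labs(x = "Number of clusters", y = "Bootstrap stability (mean ARI)") +
    theme_minimal()
}

#' Plot the modality-set x family metric grid
#'
#' AUC with bootstrap CI per family, faceted by modality set.
#'
#' @param object A `pipeline_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pipeline_result
#' @export
autoplot.pipeline_result <- function(object, ...) {
  ggplot(object$metric_grid,
         aes(x = .data$family, y = .data$auc)) +
    geom_point() +
    geom_errorbar(aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
                  width = 0.2) +
    geom_hline(yintercept = 0.5, linetype = "dashed") +
    facet_wrap(~.data$modality_set,
               labeller = ggplot2::label_both) +
    labs(x = NULL, y = "Leave-pair-out AUC (95% bootstrap CI)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot per-patient SHAP attributions
#'
#' Mean absolute contribution per feature across the explained
#' patients.
#'
#' @param object A [linear_shap()] attribution.
#' @param top_n Show at most this many features.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shap_attribution
#' @export
autoplot.shap_attribution <- function(object, top_n = 20, ...) {
  dat <- tibble(
    feature = colnames(object$contributions),
    mean_abs = colMeans(abs(object$contributions))) |>
    arrange(dplyr::desc(.data$mean_abs)) |>
    dplyr::slice_head(n = top_n) |>
    mutate(feature = factor(.data$feature, levels = rev(.data$feature)))
  ggplot(dat, aes(x = .data$feature, y = .data$mean_abs)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL,
         y = paste0("Mean |contribution| (toward ",
                    object$explained_class, ")")) +
    theme_minimal()
}
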