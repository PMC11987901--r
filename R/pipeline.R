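#' Default end-to-end pipeline configuration
#'
#' @param seed Top-level seed; every stage derives its own seed from it.
#' @param n_patients,pcr_prevalence Passed to [cohort_spec()].
#' @param modality_sets Modality sets to evaluate (subset of 1:3).
#' @param families Model families to evaluate.
#' @param mode `"paper"` or `"strict"` leakage handling.
#' @param reduced_grids Use single-point hyperparameter grids (the
#'   full default grids multiply runtime by `60 * grid size` per outer
#'   pair; single-point grids keep the demo tractable and are the
#'   documented reduced setting).
#' @param n_boot Bootstrap replicates per report.
#' @param n_inner_pairs Inner pairs per outer fold (full grids only).
#' @param output_dir Optional directory for CSV artifacts + manifest.
#' @param cluster_k_range,cluster_n_boot Radiomic clustering settings.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_patients = 57,
                            pcr_prevalence = 0.37,
                            modality_sets = 1:3,
                            families = c("logistic-lasso",
                                         "decision-tree", "linear-svm",
                                         "random-forest"),
                            mode = "paper", reduced_grids = TRUE,
                            n_boot = 1000, n_inner_pairs = 60,
                            output_dir = NULL,
                            cluster_k_range = 2:10,
                            cluster_n_boot = 50) {
  cfg <- list(seed = as.integer(seed), n_patients = n_patients,
              pcr_prevalence = pcr_prevalence,
              modality_sets = modality_sets, families = families,
              mode = mode, reduced_grids = reduced_grids,
              n_boot = n_boot, n_inner_pairs = n_inner_pairs,
              output_dir = output_dir,
              cluster_k_range = cluster_k_range,
              cluster_n_boot = cluster_n_boot)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  assert_that(is_scalar_number(cfg$seed), "seed must be a single number")
  assert_that(all(cfg$modality_sets %in% 1:3),
              "modality_sets must be a subset of 1:3")
  known <- c("logistic-lasso", "logistic-ridge", "logistic-elasticnet",
             "decision-tree", "linear-svm", "random-forest")
  assert_that(all(cfg$families %in% known),
              paste("families must be among:", paste(known, collapse = ", ")))
  assert_that(cfg$mode %in% c("paper", "strict"),
              "mode must be 'paper' or 'strict'")
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with any subset of [pipeline_config()] fields.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

# single-point grids for the reduced (tractable) setting
reduced_grid <- function(family) {
  switch(family,
    "linear-svm" = list(cost = 1),
    "logistic-lasso" = list(lambda = 0.1),
    "logistic-ridge" = list(lambda = 0.1),
    "logistic-elasticnet" = list(lambda = 0.1, alpha = 0.5),
    "decision-tree" = list(maxdepth = 3),
    "random-forest" = list(mtry_frac = NA, num_trees = 500)
  )
}

#' Run the full multimodal analysis pipeline
#'
#' Simulates (or loads) a cohort, screens every predictor against pCR,
#' clusters the radiomic features and assembles the selected feature
#' set, evaluates every requested (modality set, family) combination by
#' nested leave-pair-out cross-validation with pair-bootstrap CIs,
#' interprets the final linear model (coefficients + SHAP), and tests
#' event-free survival stratified by predicted response. Any stage
#' failure aborts with the stage name; artifacts computed so far are
#' still written when an output directory is configured.
#'
#' @param config A [pipeline_config()] (or a YAML path).
#' @return A `pipeline_result` with `cohort`, `screen`, `clusters`,
#'   `selected`, `metric_grid`, `reports`, `interpretation`, `survival`
#'   and a `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  result <- list(manifest = pipeline_manifest(config))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(config$output_dir))
        try(write_pipeline_artifacts(result, config$output_dir),
            silent = TRUE)
      abort(glue::glue("pipeline stage `{name}` failed: {conditionMessage(e)}"))
    })
  }

  cohort <- stage("simulate", generate_cohort(cohort_spec(
    n_patients = config$n_patients,
    pcr_prevalence = config$pcr_prevalence,
    seed = derive_seed(config$seed, "simulate"))))
  result$cohort <- cohort

  result$screen <- stage("screen", univariate_screen(
    cohort$table, cohort$modalities,
    mc_seed = derive_seed(config$seed, "screen")))

  result$clusters <- stage("cluster", {
    rad <- as.matrix(cohort$table[, cohort$modalities$column[
      cohort$modalities$modality == "radiomic"], drop = FALSE])
    cluster_radiomics(rad, k_range = config$cluster_k_range,
                      n_boot = config$cluster_n_boot,
                      seed = derive_seed(config$seed, "cluster"))
  })
  result$selected <- stage("select", select_features(
    cohort$table, cohort$modalities, result$clusters))

  result$reports <- stage("evaluate", {
    combos <- tidyr::expand_grid(modality_set = config$modality_sets,
                                 family = config$families)
    purrr::pmap(combos, function(modality_set, family) {
      grid <- if (config$reduced_grids) reduced_grid(family) else NULL
      spec <- model_spec(family, grid = grid)
      # every set uses the selected feature list restricted to the
      # set's modalities (set 3 = the full 17-feature-style panel)
      sources <- intersect(
        result$selected$feature,
        modality_set_sources(cohort$modalities, modality_set))
      rep <- nested_lpocv(
        cohort$table, cohort$modalities, spec, modality_set = sources,
        mode = config$mode, n_inner_pairs = config$n_inner_pairs,
        seed = derive_seed(config$seed, "evaluate",
                           modality_set * 100L + match(family,
                                                       config$families)))
      rep$modality_set <- as.character(modality_set)
      rep$bootstrap <- bootstrap_pairs(
        rep, n_boot = config$n_boot,
        seed = derive_seed(config$seed, "bootstrap",
                           modality_set * 100L + match(family,
                                                       config$families)))
      rep
    })
  })
  result$metric_grid <- stage("metric_grid", {
    purrr::map_dfr(result$reports, function(r)
      dplyr::bind_cols(
        tibble(modality_set = r$modality_set, family = r$family,
               auc = r$auc, ci_lower = r$bootstrap$ci_lower,
               ci_upper = r$bootstrap$ci_upper),
        r$metrics))
  })

  result$interpretation <- stage("interpret", {
    sources <- result$selected$feature
    fm <- prepare_design(cohort$table, cohort$modalities, sources,
                         fit_rows = seq_len(nrow(cohort$table)),
                         impute = "mice",
                         seed = derive_seed(config$seed, "interpret"))
    grid <- if (config$reduced_grids) reduced_grid("linear-svm") else NULL
    fin <- final_model(fm$matrix, cohort$table$outcome,
                       model_spec("linear-svm", grid = grid),
                       seed = derive_seed(config$seed, "final"))
    list(final = fin,
         coefficients = linear_coefficients(fin, fm$meta |>
                          dplyr::select(column = "source",
                                        "modality") |>
                          dplyr::distinct()),
         shap = linear_shap(fin, fm$matrix))
  })

  result$survival <- stage("survival", {
    pred <- ifelse(
      result$interpretation$final$per_patient$probability >= 0.5,
      "predicted pCR", "predicted non-pCR")
    tb <- cohort$table
    list(predicted_group = pred,
         km = km_estimate(tb$efs_time, tb$efs_event, pred),
         logrank = if (length(unique(pred)) == 2)
           logrank_test(tb$efs_time, tb$efs_event, pred) else NULL)
  })

  if (!is.null(config$output_dir))
    write_pipeline_artifacts(result, config$output_dir)
  structure(result, class = "pipeline_result")
}

pipeline_manifest <- function(config) {
  plain <- unclass(config)
  list(
    package_version = as.character(utils::packageVersion("pcrpet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stage_seeds = list(
      simulate = derive_seed(config$seed, "simulate"),
      screen = derive_seed(config$seed, "screen"),
      cluster = derive_seed(config$seed, "cluster"),
      interpret = derive_seed(config$seed, "interpret"),
      final = derive_seed(config$seed, "final")),
    config = plain,
    config_hash = config_hash(plain))
}

# small deterministic hash of the serialized config (no extra deps)
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(result$screen))
    readr::write_csv(result$screen, file.path(dir, "univariate_screen.csv"))
  if (!is.null(result$metric_grid))
    readr::write_csv(result$metric_grid, file.path(dir, "metric_grid.csv"))
  if (!is.null(result$interpretation))
    readr::write_csv(result$interpretation$coefficients,
                     file.path(dir, "coefficients.csv"))
  if (!is.null(result$survival))
    readr::write_csv(result$survival$km, file.path(dir, "km_curve.csv"))
  if (!is.null(result$reports)) {
    scores <- purrr::map_dfr(result$reports, function(r)
      dplyr::mutate(r$pair_scores, modality_set = r$modality_set,
                    family = r$family))
    readr::write_csv(scores, file.path(dir, "pair_scores.csv"))
  }
  yaml::write_yaml(result$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> seed ", x$manifest$seed, ", ",
      nrow(x$cohort$table), " patients\n", sep = "")
  if (!is.null(x$metric_grid)) {
    cat("metric grid:\n")
    print(as.data.frame(x$metric_grid), digits = 3)
  }
  invisible(x)
}
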