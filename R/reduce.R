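#' Bootstrap-stability hierarchical clustering of radiomic features
#'
#' Groups redundant radiomic features by average-linkage hierarchical
#' clustering on the distance `1 - |Spearman correlation|` across
#' patients. The number of clusters is chosen by partition stability:
#' for each candidate `k`, the full-data partition is compared (adjusted
#' Rand index) with partitions recomputed on patient-bootstrap
#' resamples, and the `k` maximizing the mean index wins (ties go to the
#' smallest `k`).
#'
#' @param x Numeric matrix, patients x radiomic features (named columns).
#' @param k_range Candidate cluster counts (k = 1 is excluded: a single
#'   cluster has no partition stability to measure).
#' @param n_boot Number of bootstrap resamples (>= 20).
#' @param seed Integer seed.
#' @return A `cluster_solution`: chosen `k`, feature `assignment`,
#'   `stability_profile` tibble, `representatives` (cluster medoids) and
#'   the full-data `hclust` tree.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 100, seed = 1))
#' rad <- as.matrix(coh$table[, grep("^radiomic", names(coh$table))])
#' sol <- cluster_radiomics(rad, k_range = 2:8, n_boot = 30, seed = 1)
#' sol$k
cluster_radiomics <- function(x, k_range = 2:12, n_boot = 100, seed = 1L) {
  x <- as.matrix(x)
  assert_that(ncol(x) >= 2, "need at least 2 radiomic features")
  assert_that(n_boot >= 20, "`n_boot` must be >= 20")
  k_range <- sort(unique(as.integer(k_range)))
  assert_that(all(k_range >= 2) && all(k_range < ncol(x)),
              "k_range must lie in [2, n_features - 1]")
  tree <- hclust(feature_distance(x), method = "average")
  full_parts <- lapply(k_range, function(k) cutree(tree, k))
  names(full_parts) <- k_range
  n <- nrow(x)
  scores <- matrix(NA_real_, n_boot, length(k_range),
                   dimnames = list(NULL, k_range))
  with_seed(derive_seed(seed, "cluster_boot"), {
    for (b in seq_len(n_boot)) {
      rows <- sample.int(n, n, replace = TRUE)
      tb <- hclust(feature_distance(x[rows, , drop = FALSE]),
                   method = "average")
      for (j in seq_along(k_range))
        scores[b, j] <- mclust::adjustedRandIndex(
          cutree(tb, k_range[j]), full_parts[[j]])
    }
  })
  profile <- tibble(k = k_range, stability = colMeans(scores))
  k_best <- profile$k[which.max(profile$stability)]
  assignment <- full_parts[[as.character(k_best)]]
  sol <- structure(
    list(k = k_best, assignment = assignment,
         stability_profile = profile, tree = tree),
    class = "cluster_solution"
  )
  sol$representatives <- pick_representatives(sol, x)
  sol
}

# 1 - |Spearman| feature distance; constant features are maximally distant
feature_distance <- function(x) {
  sds <- apply(x, 2, sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds)))
    warn("constant feature(s): treated as maximally distant to all others")
  rho <- suppressWarnings(cor(x, method = "spearman",
                              use = "pairwise.complete.obs"))
  d <- 1 - abs(rho)
  d[is.na(d)] <- 1
  diag(d) <- 0
  as.dist(d)
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("<cluster_solution> k = ", x$k, " over ", length(x$assignment),
      " features; stability ",
      round(max(x$stability_profile$stability), 3), "\n", sep = "")
  invisible(x)
}

#' Pick one representative feature per cluster (the medoid)
#'
#' The representative of a cluster is the member with the highest mean
#' absolute Spearman correlation to its co-members; a singleton cluster
#' represents itself. Deterministic given the matrix.
#'
#' @param solution A [cluster_radiomics()] solution.
#' @param x The feature matrix the solution was computed on.
#' @return Named character vector, cluster id -> feature name.
#' @export
pick_representatives <- function(solution, x) {
  stopifnot(inherits(solution, "cluster_solution"))
  x <- as.matrix(x)
  rho <- suppressWarnings(abs(cor(x, method = "spearman",
                                  use = "pairwise.complete.obs")))
  rho[is.na(rho)] <- 0
  asg <- solution$assignment
  reps <- vapply(sort(unique(asg)), function(g) {
    members <- names(asg)[asg == g]
    if (length(members) == 1) return(members)
    hub <- rowMeans(rho[members, members, drop = FALSE])
    members[which.max(hub)]
  }, character(1))
  setNames(reps, sort(unique(asg)))
}

#' Filter predictors by missingness
#'
#' Drops predictor columns whose missing fraction is at or above
#' `threshold` (default: half the cohort). Outcome, batch and survival
#' columns are never dropped.
#'
#' @param table A cohort tibble.
#' @param threshold Missing-fraction cutoff in (0, 1]; a column is
#'   dropped when `missing fraction >= threshold`.
#' @return List with `retained` and `dropped` column names and a
#'   per-column `report` tibble.
#' @export
filter_by_missingness <- function(table, threshold = 0.5) {
  assert_that(threshold > 0 && threshold <= 1,
              "`threshold` must be in (0, 1]")
  protected <- intersect(c("patient_id", "outcome", "batch",
                           "efs_time", "efs_event"), names(table))
  pred <- setdiff(names(table), protected)
  frac <- vapply(table[pred], function(x) mean(is.na(x)), numeric(1))
  report <- tibble(column = pred, missing_fraction = unname(frac),
                   retained = unname(frac) < threshold)
  list(retained = c(protected, pred[frac < threshold]),
       dropped = pred[frac >= threshold],
       report = report)
}

#' Single imputation by chained equations with randomized trees
#'
#' Missing entries are first filled by the column median (numeric) or
#' mode (categorical), then refined over `n_iter` sweeps in which each
#' incomplete column is regressed on all other columns with a random
#' forest and its missing entries replaced by the forest predictions.
#' Returns one completed dataset; deterministic given the seed.
#'
#' @param data A data frame or numeric matrix with missing values.
#' @param n_iter Number of chained-equation sweeps.
#' @param seed Integer seed.
#' @param num_trees Trees per forest.
#' @return The completed data, same type and shape as the input.
#' @export
#' @examples
#' df <- data.frame(a = c(1, 2, NA, 4), b = c(2, 4, 6, 8))
#' mice_impute(df, n_iter = 2, seed = 1)
mice_impute <- function(data, n_iter = 10, seed = 1L, num_trees = 100) {
  was_matrix <- is.matrix(data)
  df <- as.data.frame(data, stringsAsFactors = FALSE)
  chr <- vapply(df, is.character, logical(1))
  df[chr] <- lapply(df[chr], factor)
  miss <- vapply(df, anyNA, logical(1))
  fully_missing <- names(df)[vapply(df, function(x) all(is.na(x)),
                                    logical(1))]
  if (length(fully_missing))
    abort(paste("column(s) with no observed values:",
                paste(fully_missing, collapse = ", ")))
  if (!any(miss)) return(data)
  na_idx <- lapply(df[miss], function(x) which(is.na(x)))
  # initial fill: median / mode
  for (cl in names(df)[miss]) {
    x <- df[[cl]]
    fill <- if (is.numeric(x)) median(x, na.rm = TRUE) else {
      tb <- table(x)
      factor(names(tb)[which.max(tb)], levels = levels(x))
    }
    df[[cl]][na_idx[[cl]]] <- fill
  }
  # visit incomplete columns in order of increasing missingness
  visit <- names(sort(vapply(na_idx, length, integer(1))))
  for (it in seq_len(n_iter)) {
    for (cl in visit) {
      obs <- setdiff(seq_len(nrow(df)), na_idx[[cl]])
      if (length(obs) < 2) next
      fit <- ranger::ranger(
        x = df[obs, setdiff(names(df), cl), drop = FALSE],
        y = df[[cl]][obs],
        num.trees = num_trees,
        seed = derive_seed(seed, paste0("mice_", cl), it),
        num.threads = 1
      )
      pred <- predict(fit, df[na_idx[[cl]], setdiff(names(df), cl),
                              drop = FALSE],
                      num.threads = 1)$predictions
      df[[cl]][na_idx[[cl]]] <- pred
    }
  }
  df[chr] <- lapply(df[chr], as.character)
  if (was_matrix) as.matrix(df) else {
    if (tibble::is_tibble(data)) as_tibble(df) else df
  }
}

#' Assemble the final selected multimodal feature set
#'
#' Non-radiomic predictors come from an explicit include-list (the
#' expert-driven part of feature selection is configuration, not an
#' algorithm), filtered by missingness; radiomic predictors are the
#' cluster representatives of a [cluster_radiomics()] solution.
#'
#' @param table A cohort tibble.
#' @param modalities Column-to-modality tibble.
#' @param solution A `cluster_solution` over the radiomic columns.
#' @param include Character vector of non-radiomic columns to keep.
#' @param missingness_threshold Passed to [filter_by_missingness()].
#' @return A `selected_features` tibble with `feature` and `modality`.
#' @export
select_features <- function(table, modalities, solution,
                            include = default_nonradiomic_features(),
                            missingness_threshold = 0.5) {
  keep <- filter_by_missingness(table, missingness_threshold)$retained
  include <- intersect(include, keep)
  reps <- unname(solution$representatives)
  out <- tibble(feature = c(include, reps)) |>
    left_join(modalities, by = c(feature = "column"))
  class(out) <- c("selected_features", class(out))
  out
}

#' Default non-radiomic include-list
#'
#' Mirrors the composition of the published final predictor set:
#' 3 clinical, 2 histopathological, 3 molecular and 3 PET non-radiomic
#' features (the 6 radiomic slots are filled by cluster
#' representatives).
#'
#' @return Character vector of column names.
#' @export
default_nonradiomic_features <- function() {
  c("clinical_t_stage", "contraception", "family_history",
    "mitosis_count", "ki67_ihc",
    "ki67_mrna", "tp53_status", "ggir",
    "tumor_suvmax", "node_suvmax", "mtv")
}
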