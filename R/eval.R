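#' Enumerate all discordant (pCR, non-pCR) patient pairs
#'
#' Leave-pair-out cross-validation holds out one patient of each outcome
#' class; this enumerates every ordered pair.
#'
#' @param labels Outcome vector (`"pCR"`/`"non-pCR"`, factor, or 0/1
#'   with 1 = pCR).
#' @param ids Optional patient identifiers (default: row indices).
#' @return Tibble with `pos_id` (pCR) and `neg_id` (non-pCR); one row
#'   per pair, `n_pos * n_neg` rows total.
#' @export
#' @examples
#' nrow(enumerate_discordant_pairs(rep(c("pCR", "non-pCR"), c(21, 36))))
enumerate_discordant_pairs <- function(labels, ids = NULL) {
  pos_flag <- as_pcr_logical(labels)
  if (is.null(ids)) ids <- seq_along(labels)
  assert_that(length(ids) == length(labels),
              "`ids` must match `labels` in length")
  assert_that(any(pos_flag) && any(!pos_flag),
              "both outcome classes must be present")
  tidyr::expand_grid(pos_id = ids[pos_flag], neg_id = ids[!pos_flag])
}

# normalize an outcome vector to TRUE = pCR
as_pcr_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    assert_that(all(labels %in% c(0, 1)), "numeric labels must be 0/1")
    return(labels == 1)
  }
  lab <- as.character(labels)
  assert_that(all(lab %in% c("pCR", "non-pCR")),
              "labels must be 'pCR'/'non-pCR', 0/1, or logical")
  lab == "pCR"
}

#' Leave-pair-out AUC from per-pair held-out scores
#'
#' The fraction of discordant pairs in which the pCR patient receives
#' the higher score; ties count one half. Identical to the
#' Mann-Whitney pair-counting estimator.
#'
#' @param pair_scores Tibble with `pos_score` and `neg_score`.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' lpo_auc(tibble::tibble(pos_score = c(2, 3), neg_score = c(1, 3)))
lpo_auc <- function(pair_scores) {
  assert_that(nrow(pair_scores) >= 1, "need at least one scored pair")
  with(pair_scores,
       mean((pos_score > neg_score) + 0.5 * (pos_score == neg_score)))
}

#' Inner-loop hyperparameter selection by leave-pair-out AUC
#'
#' Samples `n_inner_pairs` discordant pairs (all pairs when fewer
#' exist) and, for every grid point, scores each pair after refitting
#' on the remaining training patients. The grid point with the highest
#' inner AUC wins; ties go to the first point in canonical grid order.
#' A single-point grid is returned unchanged without any fitting.
#'
#' @param x Numeric training matrix (patients x features), no missing
#'   values.
#' @param y Outcome vector for the training rows.
#' @param spec A [model_spec()].
#' @param n_inner_pairs Number of inner pairs to sample.
#' @param seed Integer seed (pair sampling and randomized fits).
#' @return List with `hyper` (one-row data frame), `inner_auc`, and the
#'   full `grid_auc` tibble.
#' @export
inner_select <- function(x, y, spec, n_inner_pairs = 60, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  grid <- spec$grid
  if (nrow(grid) == 1)
    return(list(hyper = grid[1, , drop = FALSE], inner_auc = NA_real_,
                grid_auc = tibble(grid_row = 1L, auc = NA_real_)))
  yl <- factor(ifelse(as_pcr_logical(y), "pCR", "non-pCR"),
               levels = c("non-pCR", "pCR"))
  pairs <- enumerate_discordant_pairs(yl)
  if (nrow(pairs) > n_inner_pairs) {
    keep <- with_seed(derive_seed(seed, "inner_pairs"),
                      sample.int(nrow(pairs), n_inner_pairs))
    pairs <- pairs[keep, ]
  }
  aucs <- vapply(seq_len(nrow(grid)), function(gi) {
    hyper <- grid[gi, , drop = FALSE]
    sc <- vapply(seq_len(nrow(pairs)), function(pi) {
      hold <- c(pairs$pos_id[pi], pairs$neg_id[pi])
      fit <- tryCatch(
        fit_one(spec$family, x[-hold, , drop = FALSE], yl[-hold], hyper,
                seed = derive_seed(seed, "inner_fit", gi * 100000L + pi)),
        error = function(e) NULL)
      if (is.null(fit)) return(c(NA_real_, NA_real_))
      score_one(spec$family, fit, x[hold, , drop = FALSE])
    }, numeric(2))
    if (anyNA(sc)) {
      warn(glue::glue("grid point {gi} failed to fit; inner auc set to 0.5"))
      return(0.5)
    }
    lpo_auc(tibble(pos_score = sc[1, ], neg_score = sc[2, ]))
  }, numeric(1))
  best <- which.max(aucs)  # which.max takes the first maximum: canonical tie-break
  list(hyper = grid[best, , drop = FALSE], inner_auc = aucs[best],
       grid_auc = tibble(grid_row = seq_len(nrow(grid)), auc = aucs))
}

#' Columns belonging to a Table-3-style modality set
#'
#' Set 1: clinical + histopathological + PET (non-radiomic);
#' set 2 adds genomic; set 3 adds radiomic.
#'
#' @param modalities Column-to-modality tibble.
#' @param modality_set 1, 2 or 3.
#' @return Character vector of source column names.
#' @export
modality_set_sources <- function(modalities, modality_set) {
  assert_that(modality_set %in% 1:3, "`modality_set` must be 1, 2 or 3")
  tags <- switch(modality_set,
                 c("clinical", "histopathological", "pet"),
                 c("clinical", "histopathological", "pet", "genomic"),
                 c("clinical", "histopathological", "pet", "genomic",
                   "radiomic"))
  modalities$column[modalities$modality %in% tags]
}

# prepare the encoded/standardized/corrected/complete design matrix;
# transform parameters are learned on fit_rows only
prepare_design <- function(table, modalities, sources, fit_rows,
                           impute = c("mice", "median"), seed = 1L,
                           impute_iter = 5) {
  impute <- match.arg(impute)
  keep <- intersect(sources, names(table))
  assert_that(length(keep) > 0, "modality set selects zero columns")
  sub <- table[, keep, drop = FALSE]
  if (anyNA(sub)) {
    if (impute == "mice") {
      sub <- mice_impute(sub, n_iter = impute_iter,
                         seed = derive_seed(seed, "design_impute"))
    } else {
      # per-fold refittable imputer: fill from fit-row median / mode
      for (cl in names(sub)) {
        x <- sub[[cl]]
        if (!anyNA(x)) next
        xf <- x[fit_rows]
        fill <- if (is.numeric(x)) median(xf, na.rm = TRUE) else {
          tb <- table(xf)
          names(tb)[which.max(tb)]
        }
        sub[[cl]][is.na(x)] <- fill
      }
    }
  }
  fm <- encode_standardize(sub, modalities, fit_rows = fit_rows)
  if ("batch" %in% names(table) &&
      any(fm$meta$modality == "genomic") &&
      length(unique(table$batch)) >= 2)
    fm <- batch_correct_mean(fm, table$batch)
  fm
}

#' Nested leave-pair-out cross-validation of one model family
#'
#' For every discordant outer pair the two patients are removed,
#' hyperparameters are chosen by [inner_select()] on the remainder, the
#' model is refit with the winners, and the held-out pair is scored.
#' The outer AUC is the pair-counting estimate over all outer pairs;
#' secondary metrics come from per-patient probabilities (the mean of a
#' patient's held-out scores; SVM margins are Platt-calibrated first)
#' thresholded at 0.5 with pCR as the positive class.
#'
#' In `"paper"` mode imputation, standardization and batch correction
#' are fit once on the full cohort (as is common at this cohort size);
#' in `"strict"` mode they are refit inside every outer fold on the 55
#' training patients only, with median/mode imputation as the per-fold
#' imputer.
#'
#' @param table Cohort tibble with `outcome` (and optionally `batch`).
#' @param modalities Column-to-modality tibble.
#' @param spec A [model_spec()].
#' @param modality_set 1, 2 or 3 (see [modality_set_sources()]), or a
#'   character vector of source columns to use directly.
#' @param mode `"paper"` or `"strict"` leakage handling.
#' @param n_inner_pairs Inner pairs per outer fold.
#' @param seed Integer seed.
#' @param impute_iter Chained-equation sweeps for paper-mode imputation.
#' @return An `eval_report`: `pair_scores`, `auc`, `per_patient`,
#'   `metrics`, `chosen_hyper`, plus family/modality-set/mode/seed.
#' @export
nested_lpocv <- function(table, modalities, spec, modality_set = 3,
                         mode = c("paper", "strict"),
                         n_inner_pairs = 60, seed = 1L, impute_iter = 5) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "model_spec"))
  sources <- if (is.character(modality_set)) modality_set else
    modality_set_sources(modalities, modality_set)
  set_label <- if (is.character(modality_set)) "custom" else
    as.character(modality_set)
  y <- factor(ifelse(as_pcr_logical(table$outcome), "pCR", "non-pCR"),
              levels = c("non-pCR", "pCR"))
  n <- nrow(table)
  pairs <- enumerate_discordant_pairs(y)
  if (mode == "paper") {
    fm_full <- prepare_design(table, modalities, sources,
                              fit_rows = seq_len(n), impute = "mice",
                              seed = seed, impute_iter = impute_iter)
  }
  scores <- matrix(NA_real_, nrow(pairs), 2)
  hyper_rows <- integer(nrow(pairs))
  score_sum <- numeric(n); score_cnt <- integer(n)
  for (pi in seq_len(nrow(pairs))) {
    hold <- c(pairs$pos_id[pi], pairs$neg_id[pi])
    train <- setdiff(seq_len(n), hold)
    if (mode == "paper") {
      xtr <- fm_full$matrix[train, , drop = FALSE]
      xte <- fm_full$matrix[hold, , drop = FALSE]
    } else {
      fm <- suppressWarnings(
        prepare_design(table, modalities, sources, fit_rows = train,
                       impute = "median", seed = seed))
      xtr <- fm$matrix[train, , drop = FALSE]
      xte <- fm$matrix[hold, , drop = FALSE]
    }
    sel <- inner_select(xtr, y[train], spec, n_inner_pairs,
                        seed = derive_seed(seed, "outer", pi))
    fit <- fit_one(spec$family, xtr, y[train], sel$hyper,
                   seed = derive_seed(seed, "outer_fit", pi))
    sc <- score_one(spec$family, fit, xte)
    scores[pi, ] <- sc
    hyper_rows[pi] <- which(apply(spec$grid, 1, function(r)
      isTRUE(all.equal(unlist(r), unlist(sel$hyper)))))[1]
    score_sum[hold] <- score_sum[hold] + sc
    score_cnt[hold] <- score_cnt[hold] + 1L
  }
  pair_scores <- dplyr::bind_cols(pairs,
                                  tibble(pos_score = scores[, 1],
                                         neg_score = scores[, 2]))
  per_patient <- tibble(
    patient = seq_len(n),
    patient_id = if ("patient_id" %in% names(table)) table$patient_id else
      as.character(seq_len(n)),
    outcome = as.character(y),
    mean_score = score_sum / score_cnt
  )
  per_patient$probability <- calibrate_scores(
    spec$family, per_patient$mean_score, y)
  rep <- structure(
    list(family = spec$family, modality_set = set_label, mode = mode,
         seed = as.integer(seed), pair_scores = pair_scores,
         auc = lpo_auc(pair_scores), per_patient = per_patient,
         metrics = classification_metrics(y, per_patient$probability),
         chosen_hyper = tibble(pair = seq_len(nrow(pairs)),
                               grid_row = hyper_rows)),
    class = "eval_report")
  rep
}

# map aggregated scores to probabilities: Platt calibration for svm
# margins, identity for families that already emit probabilities
calibrate_scores <- function(family, score, y) {
  if (family != "linear-svm") return(score)
  df <- data.frame(s = score, y = y == "pCR")
  fit <- suppressWarnings(glm(y ~ s, binomial, df))
  unname(predict(fit, df, type = "response"))
}

# confusion metrics at threshold 0.5, pCR positive
classification_metrics <- function(y, probability, threshold = 0.5) {
  truth <- y == "pCR"
  pred <- probability >= threshold
  tp <- sum(pred & truth); tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  tibble(
    accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", x$family, ", modality set ", x$modality_set,
      " (", x$mode, " mode)\n", sep = "")
  cat("  outer pairs: ", nrow(x$pair_scores),
      "; AUC = ", round(x$auc, 3), "\n", sep = "")
  m <- x$metrics
  cat(sprintf("  acc %.2f | se %.2f | sp %.2f | ppv %.2f | npv %.2f\n",
              m$accuracy, m$sensitivity, m$specificity, m$ppv, m$npv))
  invisible(x)
}

#' Outcome-stratified pair bootstrap of the leave-pair-out AUC
#'
#' Each replicate resamples pCR patients and non-pCR patients
#' separately with replacement, induces the discordant-pair multiset,
#' and recomputes the AUC from the stored per-pair scores. The 95% CI
#' is the percentile interval. For a comparison of two reports on the
#' same cohort the AUC difference is computed on shared replicates and
#' the two-sided p-value is `2 * min(P(diff <= 0), P(diff >= 0))`,
#' floored at `2 / n_boot`.
#'
#' @param report An `eval_report` (or anything with a `pair_scores`
#'   tibble).
#' @param report_b Optional second report for a paired comparison.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return A `bootstrap_result`: `auc`, `ci_lower`, `ci_upper`,
#'   `replicates`; for comparisons also `auc_b`, `diff`, `diff_ci_*`,
#'   `p_value`, `diff_replicates`.
#' @export
bootstrap_pairs <- function(report, report_b = NULL, n_boot = 10000,
                            seed = 1L) {
  if (n_boot < 100) warn("n_boot < 100: bootstrap CI will be unstable")
  ca <- win_matrix(report$pair_scores)
  if (!is.null(report_b)) {
    cb <- win_matrix(report_b$pair_scores)
    assert_that(identical(dimnames(ca), dimnames(cb)),
                "comparison reports must share the same cohort")
  }
  n_pos <- nrow(ca); n_neg <- ncol(ca)
  reps_a <- numeric(n_boot)
  reps_b <- if (is.null(report_b)) NULL else numeric(n_boot)
  with_seed(derive_seed(seed, "pair_boot"), {
    for (b in seq_len(n_boot)) {
      wp <- tabulate(sample.int(n_pos, n_pos, replace = TRUE), n_pos)
      wn <- tabulate(sample.int(n_neg, n_neg, replace = TRUE), n_neg)
      denom <- n_pos * n_neg
      reps_a[b] <- as.numeric(wp %*% ca %*% wn) / denom
      if (!is.null(report_b))
        reps_b[b] <- as.numeric(wp %*% cb %*% wn) / denom
    }
  })
  out <- list(auc = lpo_auc(report$pair_scores),
              ci_lower = unname(quantile(reps_a, 0.025)),
              ci_upper = unname(quantile(reps_a, 0.975)),
              n_boot = as.integer(n_boot), replicates = reps_a)
  if (!is.null(report_b)) {
    d <- reps_a - reps_b
    p <- 2 * min(mean(d <= 0), mean(d >= 0))
    out$auc_b <- lpo_auc(report_b$pair_scores)
    out$diff <- out$auc - out$auc_b
    out$diff_ci_lower <- unname(quantile(d, 0.025))
    out$diff_ci_upper <- unname(quantile(d, 0.975))
    out$p_value <- max(min(p, 1), 2 / n_boot)
    out$diff_replicates <- d
  }
  structure(out, class = "bootstrap_result")
}

# pairwise win matrix: rows = pCR patients, cols = non-pCR patients
win_matrix <- function(pair_scores) {
  pos <- sort(unique(pair_scores$pos_id))
  neg <- sort(unique(pair_scores$neg_id))
  C <- matrix(NA_real_, length(pos), length(neg),
              dimnames = list(as.character(pos), as.character(neg)))
  w <- (pair_scores$pos_score > pair_scores$neg_score) +
    0.5 * (pair_scores$pos_score == pair_scores$neg_score)
  C[cbind(match(pair_scores$pos_id, pos),
          match(pair_scores$neg_id, neg))] <- w
  assert_that(!anyNA(C), "pair scores must cover every discordant pair")
  C
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> AUC %.3f (95%% CI %.3f-%.3f), %d reps\n",
              x$auc, x$ci_lower, x$ci_upper, x$n_boot))
  if (!is.null(x$p_value))
    cat(sprintf("  vs B: AUC %.3f, diff %+.3f (%.3f-%.3f), p = %.4f\n",
                x$auc_b, x$diff, x$diff_ci_lower, x$diff_ci_upper,
                x$p_value))
  invisible(x)
}

#' Final model: full-cohort refit plus standard leave-pair-out scores
#'
#' Refits the chosen family on all patients for interpretation and
#' estimates per-patient held-out probabilities by a standard
#' (non-nested) LPOCV with the fixed hyperparameters.
#'
#' @param x Complete numeric design matrix (patients x features).
#' @param y Outcome vector.
#' @param spec A [model_spec()].
#' @param hyper One-row hyperparameter data frame; default: first grid
#'   row for a single-point grid, otherwise chosen by [inner_select()]
#'   on the full data.
#' @param seed Integer seed.
#' @param lpocv If `TRUE` (default), also estimate per-patient held-out
#'   probabilities and an LPOCV AUC; `FALSE` skips the pair loop (one
#'   model fit per discordant pair) when only the full-cohort fit and
#'   its coefficients are needed.
#' @return A `final_model`: fitted `model`, `hyper`, `pair_scores`,
#'   `auc`, `per_patient` and (for linear families) `coefficients`.
#' @export
final_model <- function(x, y, spec, hyper = NULL, seed = 1L,
                        lpocv = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  yl <- factor(ifelse(as_pcr_logical(y), "pCR", "non-pCR"),
               levels = c("non-pCR", "pCR"))
  if (is.null(hyper))
    hyper <- inner_select(x, yl, spec,
                          seed = derive_seed(seed, "final_select"))$hyper
  model <- fit_one(spec$family, x, yl, hyper,
                   seed = derive_seed(seed, "final_fit"))
  pair_scores <- NULL
  auc <- NA_real_
  per_patient <- NULL
  if (isTRUE(lpocv)) {
    pairs <- enumerate_discordant_pairs(yl)
    n <- nrow(x)
    score_sum <- numeric(n); score_cnt <- integer(n)
    sc <- matrix(NA_real_, nrow(pairs), 2)
    for (pi in seq_len(nrow(pairs))) {
      hold <- c(pairs$pos_id[pi], pairs$neg_id[pi])
      fit <- fit_one(spec$family, x[-hold, , drop = FALSE], yl[-hold],
                     hyper, seed = derive_seed(seed, "lpocv_fit", pi))
      s <- score_one(spec$family, fit, x[hold, , drop = FALSE])
      sc[pi, ] <- s
      score_sum[hold] <- score_sum[hold] + s
      score_cnt[hold] <- score_cnt[hold] + 1L
    }
    pair_scores <- dplyr::bind_cols(pairs, tibble(pos_score = sc[, 1],
                                                  neg_score = sc[, 2]))
    auc <- lpo_auc(pair_scores)
    per_patient <- tibble(
      patient = seq_len(n), outcome = as.character(yl),
      mean_score = score_sum / score_cnt)
    per_patient$probability <- calibrate_scores(
      spec$family, per_patient$mean_score, yl)
  }
  structure(
    list(family = spec$family, model = model, hyper = hyper,
         pair_scores = pair_scores, auc = auc,
         per_patient = per_patient,
         coefficients = coef_one(spec$family, model, colnames(x)),
         feature_names = colnames(x), seed = as.integer(seed),
         training_mean = colMeans(x)),
    class = "final_model")
}

#' @export
print.final_model <- function(x, ...) {
  cat("<final_model> ", x$family, " on ", length(x$feature_names),
      " features; LPOCV AUC = ", round(x$auc, 3), "\n", sep = "")
  invisible(x)
}
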