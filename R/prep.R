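#' One-hot encode and standardize a multimodal cohort table
#'
#' Categorical predictors become 0/1 indicator blocks (one column per
#' level observed in the fitting rows); numeric predictors are centered
#' and scaled to unit variance. All parameters (category levels, means,
#' standard deviations) are learned on `fit_rows` only and applied to
#' every row, so the transform can be fit inside a cross-validation fold
#' without leakage. Missing values propagate as `NA`. Meta columns
#' (patient id, outcome, batch, survival) are never encoded.
#'
#' @param table A cohort tibble.
#' @param modalities Tibble with `column` and `modality` (as produced by
#'   [generate_cohort()] / [read_cohort()]).
#' @param fit_rows Integer row indices used to learn the parameters
#'   (default: all rows).
#' @return A `feature_matrix`: list with numeric `matrix` (patients x
#'   encoded features) and `meta` tibble (encoded column, source column,
#'   modality, encoding, center, scale).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(seed = 1))
#' fm <- encode_standardize(coh$table, coh$modalities)
#' round(colMeans(fm$matrix[, 1:3], na.rm = TRUE), 9)
encode_standardize <- function(table, modalities, fit_rows = NULL) {
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(table))
  assert_that(length(fit_rows) > 0, "`fit_rows` must be nonempty")
  pred_cols <- modalities$column[modalities$modality != "meta"]
  pred_cols <- intersect(pred_cols, names(table))
  cols <- list(); meta <- list()
  for (cl in pred_cols) {
    x <- table[[cl]]
    mod <- modalities$modality[modalities$column == cl]
    if (is.numeric(x)) {
      ctr <- mean(x[fit_rows], na.rm = TRUE)
      scl <- sd(x[fit_rows], na.rm = TRUE)
      if (is.na(scl) || scl == 0) {
        warn(glue::glue("zero-variance column `{cl}` passed through as 0"))
        z <- ifelse(is.na(x), NA_real_, 0)
        scl <- NA_real_
      } else z <- (x - ctr) / scl
      cols[[cl]] <- z
      meta[[cl]] <- tibble(column = cl, source = cl, modality = mod,
                           encoding = "standardized",
                           center = ctr, scale = scl)
    } else {
      levs <- sort(unique(as.character(x[fit_rows])))
      levs <- levs[!is.na(levs)]
      seen <- unique(as.character(x))
      unseen <- setdiff(seen[!is.na(seen)], levs)
      if (length(unseen))
        warn(glue::glue(
          "column `{cl}`: level(s) {paste(unseen, collapse = ', ')} unseen ",
          "at fit time encode as an all-zero block"))
      for (lv in levs) {
        nm <- paste0(cl, "=", lv)
        cols[[nm]] <- ifelse(is.na(x), NA_real_,
                             as.numeric(as.character(x) == lv))
        meta[[nm]] <- tibble(column = nm, source = cl, modality = mod,
                             encoding = "one-hot",
                             center = NA_real_, scale = NA_real_)
      }
    }
  }
  structure(
    list(matrix = do.call(cbind, cols),
         meta = dplyr::bind_rows(meta),
         fit_rows = fit_rows),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$matrix), " patients x ",
      ncol(x$matrix), " encoded features (",
      sum(is.na(x$matrix)), " missing values)\n", sep = "")
  invisible(x)
}

#' Mean-only batch correction for genomic expression columns
#'
#' Removes additive batch location shifts from the genomic columns of a
#' feature matrix, in the spirit of mean-only ComBat: per feature and
#' batch the deviation of the batch mean from the grand mean is
#' subtracted. With `shrink = TRUE` the batch deviations are shrunk by an
#' empirical-Bayes weighting of the per-feature residual variance against
#' the across-feature spread of batch deviations. Non-genomic columns are
#' never modified.
#'
#' @param fm A [encode_standardize()]d `feature_matrix`.
#' @param batch_labels Character/factor vector, one label per patient.
#' @param shrink Apply empirical-Bayes shrinkage to the batch deviations.
#' @param modality Which modality tag to correct (default `"genomic"`).
#' @return The corrected `feature_matrix`.
#' @export
batch_correct_mean <- function(fm, batch_labels, shrink = FALSE,
                               modality = "genomic") {
  stopifnot(inherits(fm, "feature_matrix"))
  batch_labels <- as.character(batch_labels)
  assert_that(length(batch_labels) == nrow(fm$matrix),
              "one batch label per patient required")
  tabs <- table(batch_labels)
  assert_that(length(tabs) >= 2, "need at least 2 batches")
  singletons <- names(tabs)[tabs < 2]
  if (length(singletons))
    warn(glue::glue("singleton batch(es) excluded from shrinkage: ",
                    "{paste(singletons, collapse = ', ')}"))
  gcols <- fm$meta$column[fm$meta$modality == modality &
                            fm$meta$encoding == "standardized"]
  if (!length(gcols)) return(fm)
  X <- fm$matrix[, gcols, drop = FALSE]
  grand <- colMeans(X, na.rm = TRUE)
  batches <- names(tabs)
  # raw batch deviations: features x batches
  dev <- sapply(batches, function(b)
    colMeans(X[batch_labels == b, , drop = FALSE], na.rm = TRUE) - grand)
  dev <- matrix(dev, ncol = length(batches),
                dimnames = list(gcols, batches))
  if (shrink) {
    resid <- X
    for (b in batches)
      resid[batch_labels == b, ] <-
        sweep(X[batch_labels == b, , drop = FALSE], 2,
              grand + dev[, b])
    s2 <- apply(resid, 2, var, na.rm = TRUE)
    for (b in setdiff(batches, singletons)) {
      gbar <- mean(dev[, b])
      tau2 <- max(var(dev[, b]), 1e-12)
      nb <- tabs[[b]]
      dev[, b] <- (nb * tau2 * dev[, b] + s2 * gbar) / (nb * tau2 + s2)
    }
  }
  for (b in batches)
    X[batch_labels == b, ] <-
      sweep(X[batch_labels == b, , drop = FALSE], 2, dev[, b])
  fm$matrix[, gcols] <- X
  fm
}

#' Wilcoxon rank-sum test between two groups
#'
#' Mid-ranks for ties; the exact null distribution when both groups have
#' at most 12 observations and there are no ties, otherwise the normal
#' approximation with tie and continuity correction. Missing values are
#' dropped.
#'
#' @param x0,x1 Numeric vectors for the two groups.
#' @return Tibble with `statistic` (rank-sum W), `p_value`, `method`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value  # 1/3
wilcoxon_rank_sum <- function(x0, x1) {
  x0 <- x0[!is.na(x0)]; x1 <- x1[!is.na(x1)]
  assert_that(length(x0) > 0 && length(x1) > 0,
              "both groups must be nonempty")
  if (length(unique(c(x0, x1))) == 1L)
    return(tibble(statistic = NA_real_, p_value = 1,
                  method = "degenerate (all values identical)"))
  wt <- suppressWarnings(wilcox.test(x0, x1, exact = NULL, correct = TRUE))
  tibble(statistic = unname(wt$statistic), p_value = min(1, wt$p.value),
         method = wt$method)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value as the sum of hypergeometric probabilities of all
#' tables with the same margins whose probability does not exceed the
#' observed one.
#'
#' @param a,b,c,d Cell counts, row-wise: `[[a, b], [c, d]]`.
#' @return Tibble with `p_value` and `odds_ratio` (conditional MLE).
#' @export
#' @examples
#' fisher_exact_2x2(13, 14, 23, 7)$p_value  # ~0.032
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  assert_that(all(cells >= 0) && all(cells == round(cells)),
              "cell counts must be nonnegative integers")
  m <- matrix(cells, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warn("zero margin: p = 1 by convention")
    return(tibble(p_value = 1, odds_ratio = NA_real_))
  }
  ft <- fisher.test(m)
  tibble(p_value = min(1, ft$p.value), odds_ratio = unname(ft$estimate))
}

#' Univariate association screen of every predictor with pCR
#'
#' Continuous predictors are tested with the Wilcoxon rank-sum test and
#' summarized as median (Q1, Q3) per outcome group; categorical
#' predictors with Fisher's exact test (exact network enumeration; for
#' large sparse tables a seeded Monte-Carlo p-value) and summarized as
#' counts (percent). Raw (unadjusted) p-values are reported, matching
#' common univariate screening practice at this cohort size.
#'
#' @param table A cohort tibble with an `outcome` column
#'   (`"pCR"`/`"non-pCR"`).
#' @param modalities Column-to-modality tibble.
#' @param mc_seed Seed for Monte-Carlo Fisher p-values on large tables.
#' @return A `univariate_screen` tibble: feature, modality, type, test,
#'   group summaries, `p_value` and a 2-decimal `p_display`.
#' @export
univariate_screen <- function(table, modalities, mc_seed = 1L) {
  assert_that("outcome" %in% names(table), "`outcome` column required")
  assert_that(!anyNA(table$outcome), "outcome must be non-missing")
  y <- table$outcome == "pCR"
  pred_cols <- intersect(modalities$column[modalities$modality != "meta"],
                         names(table))
  rows <- purrr::map(pred_cols, function(cl) {
    x <- table[[cl]]
    mod <- modalities$modality[modalities$column == cl]
    if (length(unique(x[!is.na(x)])) < 2)
      return(tibble(feature = cl, modality = mod, type = NA_character_,
                    test = "skipped (<2 distinct values)",
                    summary_non_pcr = NA_character_,
                    summary_pcr = NA_character_, p_value = NA_real_))
    if (is.numeric(x)) {
      res <- wilcoxon_rank_sum(x[!y], x[y])
      summ <- function(v) {
        q <- quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE)
        sprintf("%.1f (%.1f, %.1f)", q[2], q[1], q[3])
      }
      tibble(feature = cl, modality = mod, type = "continuous",
             test = "wilcoxon", summary_non_pcr = summ(x[!y]),
             summary_pcr = summ(x[y]), p_value = res$p_value)
    } else {
      x <- factor(as.character(x))  # drop unused levels
      tab <- table(x, factor(ifelse(y, "pCR", "non-pCR"),
                             levels = c("non-pCR", "pCR")))
      p <- tryCatch(fisher.test(tab)$p.value, error = function(e) {
        with_seed(mc_seed,
                  fisher.test(tab, simulate.p.value = TRUE, B = 1e5)$p.value)
      })
      p <- min(1, p)
      summ <- function(col) {
        n <- tab[, col]
        paste(sprintf("%s: %d (%.1f)", rownames(tab), n,
                      100 * n / sum(n)), collapse = "; ")
      }
      tibble(feature = cl, modality = mod, type = "categorical",
             test = "fisher", summary_non_pcr = summ("non-pCR"),
             summary_pcr = summ("pCR"), p_value = p)
    }
  })
  out <- dplyr::bind_rows(rows) |>
    mutate(p_display = ifelse(is.na(.data$p_value), NA_character_,
                              sprintf("%.2f", .data$p_value)))
  class(out) <- c("univariate_screen", class(out))
  out
}
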