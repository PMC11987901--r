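#' Specification of a synthetic multimodal cohort
#'
#' Defines the generative model for a neoadjuvant TNBC cohort: latent
#' patient factors drive both the observed multimodal features and the
#' log-odds of pathological complete response (pCR), so every downstream
#' stage can be tested against known ground truth.
#'
#' Latent factors (iid standard normal per patient):
#' * `size` — tumor burden; thresholded into clinical T-stage, loads on MTV.
#' * `proliferation` — drives the four cell-cycle genes (CDC2, CDC20,
#'   KPNA2, MYBL2), their GGIr composite, and Ki-67 mRNA.
#' * `uptake` — drives tumor SUVmax.
#' * `fh` — thresholded into family history of breast cancer.
#' * `rad1` ... `radK` — one factor per planted radiomic feature cluster.
#'
#' `effect_vector` is a named vector of signed weights on these latents;
#' the label is Bernoulli with logit `alpha + sum(effect * latent)`, with
#' `alpha` solved numerically so the marginal prevalence equals
#' `pcr_prevalence`. Default weights point in the directions reported for
#' this disease setting: larger tumors respond less, more proliferative
#' and more FDG-avid tumors respond more.
#'
#' @param n_patients Cohort size.
#' @param pcr_prevalence Marginal pCR fraction in (0, 1).
#' @param effect_vector Named signed weights on the latent factors.
#' @param genomic_batch_shifts Numeric vector of additive expression-unit
#'   offsets, one per batch; patients are assigned to batches in blocks.
#' @param radiomic_cluster_plan List with `n_clusters`,
#'   `features_per_cluster` and `within_correlation` for the planted
#'   radiomic correlation blocks.
#' @param missingness_rates Named per-column missing fractions in [0, 1).
#' @param survival_params List with `baseline_hazard` (events/month for
#'   true pCR) and `hazard_ratio` (> 0) for true non-pCR.
#' @param censoring_rate Target fraction of censored patients in [0, 1).
#' @param seed Integer seed.
#' @return A `cohort_spec` object.
#' @export
#' @examples
#' spec <- cohort_spec(n_patients = 57, seed = 1)
cohort_spec <- function(n_patients = 57,
                        pcr_prevalence = 0.37,
                        effect_vector = c(size = -0.6, proliferation = 0.9,
                                          uptake = 0.5, fh = -0.4,
                                          rad1 = -0.5, rad2 = 0.4),
                        genomic_batch_shifts = c(batch1 = 0, batch2 = 150),
                        radiomic_cluster_plan = list(
                          n_clusters = 6, features_per_cluster = 5,
                          within_correlation = 0.8),
                        missingness_rates = c(ki67_mrna = 0.23,
                                              family_history = 0.02,
                                              contraception = 0.02),
                        survival_params = list(baseline_hazard = 0.004,
                                               hazard_ratio = 4),
                        censoring_rate = 0.7,
                        seed = 1L) {
  assert_that(pcr_prevalence > 0 && pcr_prevalence < 1,
              "`pcr_prevalence` must be in (0, 1)")
  assert_that(all(missingness_rates >= 0 & missingness_rates < 1),
              "missingness rates must be in [0, 1)")
  assert_that(survival_params$hazard_ratio > 0, "hazard ratio must be > 0")
  assert_that(length(genomic_batch_shifts) >= 1, "need at least one batch")
  k <- radiomic_cluster_plan$n_clusters
  known <- c("size", "proliferation", "uptake", "fh", paste0("rad", seq_len(k)))
  bad <- setdiff(names(effect_vector), known)
  if (length(bad))
    abort(paste("unknown latent(s) in effect_vector:",
                paste(bad, collapse = ", ")))
  structure(
    list(n_patients = as.integer(n_patients),
         pcr_prevalence = pcr_prevalence,
         effect_vector = effect_vector,
         genomic_batch_shifts = genomic_batch_shifts,
         radiomic_cluster_plan = radiomic_cluster_plan,
         missingness_rates = missingness_rates,
         survival_params = survival_params,
         censoring_rate = censoring_rate,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# P(pCR) marginalized over eta ~ N(0, s^2): grid quadrature
marginal_prevalence <- function(alpha, s) {
  if (s == 0) return(plogis(alpha))
  x <- seq(-8, 8, length.out = 2001)
  w <- stats::dnorm(x)
  sum(w * plogis(alpha + s * x)) / sum(w)
}

solve_intercept <- function(prevalence, s) {
  uniroot(function(a) marginal_prevalence(a, s) - prevalence,
          c(-20, 20), tol = 1e-10)$root
}

#' Bayes-optimal AUC implied by a planted effect vector
#'
#' The best achievable AUC of any classifier on the latent scale, given
#' labels drawn from the logistic model of [cohort_spec()]. Computed by
#' deterministic quadrature over the latent linear predictor.
#'
#' @param spec A [cohort_spec()], or a numeric effect norm.
#' @return The Bayes AUC as a single number in [0.5, 1].
#' @export
#' @examples
#' planted_bayes_auc(cohort_spec())
planted_bayes_auc <- function(spec) {
  s <- if (inherits(spec, "cohort_spec")) {
    sqrt(sum(spec$effect_vector^2))
  } else as.numeric(spec)
  prev <- if (inherits(spec, "cohort_spec")) spec$pcr_prevalence else 0.5
  if (s == 0) return(0.5)
  alpha <- solve_intercept(prev, s)
  x <- seq(-8, 8, length.out = 1201)
  dx <- x[2] - x[1]
  f <- stats::dnorm(x)
  p <- plogis(alpha + s * x)
  f1 <- f * p; f0 <- f * (1 - p)
  f1 <- f1 / sum(f1 * dx); f0 <- f0 / sum(f0 * dx)
  # P(eta1 > eta0) + 0.5 P(equal) over the discretized densities
  cum0 <- cumsum(f0 * dx)
  sum(f1 * dx * (cum0 - 0.5 * f0 * dx))
}

#' Scale a planted effect vector to reach a target Bayes AUC
#'
#' @param spec A [cohort_spec()].
#' @param target_auc Desired Bayes AUC on the latent scale.
#' @return The spec with `effect_vector` rescaled.
#' @export
scale_effect_to_auc <- function(spec, target_auc) {
  stopifnot(inherits(spec, "cohort_spec"))
  assert_that(target_auc > 0.5 && target_auc < 1,
              "`target_auc` must be in (0.5, 1)")
  base <- spec$effect_vector / sqrt(sum(spec$effect_vector^2))
  f <- function(s) {
    sp <- spec; sp$effect_vector <- base * s
    planted_bayes_auc(sp) - target_auc
  }
  s <- uniroot(f, c(1e-3, 25), tol = 1e-6)$root
  spec$effect_vector <- base * s
  spec
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic multimodal cohort with known ground truth
#'
#' Draws a per-patient feature table (clinical, histopathological,
#' genomic, PET non-radiomic and radiomic columns), a pCR outcome from the
#' planted logistic model, batch-shifted gene expression, planted radiomic
#' correlation blocks, exponential event-free-survival times with a
#' proportional hazard on the true label, and per-patient phantom
#' specifications for image-level testing.
#'
#' @param spec A [cohort_spec()].
#' @return A list with:
#' * `table` — tibble, one row per patient (`cohort_table`);
#' * `modalities` — tibble mapping each column to its modality tag;
#' * `truth` — planted ground truth (labels before missingness, effect
#'   vector, cluster assignment of radiomic features, batch assignment,
#'   uncensored event times, latent factor matrix);
#' * `phantom_specs` — list of [phantom_spec()], one per patient.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 57, seed = 1))
#' table(coh$table$outcome)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  plan <- spec$radiomic_cluster_plan
  k <- plan$n_clusters
  latent_names <- c("size", "proliferation", "uptake", "fh",
                    paste0("rad", seq_len(k)))
  eff <- setNames(numeric(length(latent_names)), latent_names)
  eff[names(spec$effect_vector)] <- spec$effect_vector
  if (all(eff == 0))
    warn("degenerate effect vector (all zeros): labels are pure noise")

  with_seed(derive_seed(spec$seed, "cohort"), {
    z <- matrix(rnorm(n * length(latent_names)), n,
                dimnames = list(NULL, latent_names))
    eta <- drop(z %*% eff)
    s <- sqrt(sum(eff^2))
    alpha <- if (s > 0) solve_intercept(spec$pcr_prevalence, s) else
      qlogis(spec$pcr_prevalence)
    label <- rbinom(n, 1, plogis(alpha + eta))

    batches <- names(spec$genomic_batch_shifts)
    batch <- batches[ceiling(seq_len(n) / (n / length(batches)))]

    # clinical
    age <- round(rnorm(n, 54, 12))
    t_stage <- ifelse(z[, "size"] > stats::qnorm(1 - 0.526), "T3-T4", "T1-T2")
    n_stage <- ifelse(runif(n) < 0.579, "N+", "N0")
    fam <- ifelse(z[, "fh"] > stats::qnorm(1 - 0.18), "yes", "no")
    contraception <- ifelse(runif(n) < 0.5, "yes", "no")
    multifocal <- ifelse(runif(n) < 0.3, "yes", "no")
    regimen <- ifelse(runif(n) < 8 / 57, "EC-D", "SIM")

    # histopathological
    histo_type <- ifelse(runif(n) < 0.088, "metaplastic", "non-specific")
    grade <- ifelse(runif(n) < 0.088, "grade1-2", "grade3")
    mitosis_count <- pmax(0, round(18 + 11 * rnorm(n)))
    ki67_ihc <- clip(round(40 + 25 * rnorm(n)), 0, 100)

    # genomic: four cell-cycle genes on a shared proliferation factor
    gene_med <- c(cdc2 = 130, cdc20 = 600, kpna2 = 300, mybl2 = 320)
    genes <- sapply(names(gene_med), function(g)
      exp(log(gene_med[[g]]) +
            0.7 * (0.8 * z[, "proliferation"] + 0.6 * rnorm(n))))
    shift <- spec$genomic_batch_shifts[batch]
    genes <- genes + shift  # additive batch offsets on expression scale
    genes[genes < 1] <- 1
    ggir <- rowMeans(scale(genes))
    ki67_mrna <- pmax(1, 520 + 300 *
                        (0.6 * z[, "proliferation"] + 0.8 * rnorm(n)))
    tp53 <- ifelse(runif(n) < 0.088, "wild-type", "mutated")

    # PET non-radiomic
    tumor_suvmax <- exp(log(10) + 0.45 * (0.8 * z[, "uptake"] +
                                            0.6 * rnorm(n)))
    mtv <- exp(log(7.9) + 0.7 * (0.6 * z[, "size"] + 0.8 * rnorm(n)))
    node_present <- runif(n) < 0.579
    node_suvmax <- ifelse(node_present, exp(log(4) + 0.6 * rnorm(n)), 0)

    # radiomic correlation blocks on the rad* factors
    rho <- plan$within_correlation
    m <- plan$features_per_cluster
    rad_cols <- list()
    cluster_assignment <- character(0)
    for (g in seq_len(k)) {
      for (j in seq_len(m)) {
        sgn <- if (j %% 2 == 0) -1 else 1  # sign flips within blocks
        nm <- sprintf("radiomic_c%d_f%d", g, j)
        rad_cols[[nm]] <- sgn * (sqrt(rho) * z[, paste0("rad", g)] +
                                   sqrt(1 - rho) * rnorm(n))
        cluster_assignment[nm] <- g
      }
    }

    # exponential EFS with proportional hazard on the true label
    lam <- spec$survival_params$baseline_hazard *
      ifelse(label == 1, 1, spec$survival_params$hazard_ratio)
    t_event <- rexp(n, lam)
    cmax <- censor_window(lam, spec$censoring_rate)
    c_time <- runif(n, 0, cmax)
    efs_time <- pmin(t_event, c_time)
    efs_event <- as.integer(t_event <= c_time)

    table <- tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      age = age, family_history = fam, contraception = contraception,
      clinical_t_stage = t_stage, clinical_n_stage = n_stage,
      multifocal = multifocal, regimen = regimen,
      histological_type = histo_type, histological_grade = grade,
      mitosis_count = mitosis_count, ki67_ihc = ki67_ihc,
      cdc2 = genes[, "cdc2"], cdc20 = genes[, "cdc20"],
      kpna2 = genes[, "kpna2"], mybl2 = genes[, "mybl2"],
      ggir = ggir, ki67_mrna = ki67_mrna, tp53_status = tp53,
      tumor_suvmax = tumor_suvmax, node_suvmax = node_suvmax, mtv = mtv,
      !!!rad_cols,
      outcome = ifelse(label == 1, "pCR", "non-pCR"),
      batch = batch, efs_time = efs_time, efs_event = efs_event
    )
  })

  modalities <- cohort_modalities(names(table), names(rad_cols))
  phantoms <- lapply(seq_len(n), function(i) {
    r <- (3 * mtv[i] * 1000 / (4 * pi))^(1 / 3)  # sphere-equivalent, mm
    r <- clip(r, 6, 28)
    phantom_spec(tumor_radii = r * c(1.15, 1, 0.87),
                 peak_uptake = tumor_suvmax[i],
                 heterogeneity_scale = 0.15, noise_sd = 0.05,
                 seed = derive_seed(spec$seed, "phantom", i))
  })
  truth <- list(
    true_labels = label,
    planted_coefficients = eff,
    intercept = alpha,
    cluster_assignment = cluster_assignment,
    batch_assignment = setNames(batch, table$patient_id),
    true_event_times = t_event,
    latents = z,
    bayes_auc = planted_bayes_auc(spec),
    degenerate_effects = all(eff == 0)
  )
  out <- list(table = table, modalities = modalities, truth = truth,
              phantom_specs = phantoms, spec = spec)
  if (length(spec$missingness_rates))
    out$table <- inject_missingness(out$table, spec$missingness_rates,
                                    seed = derive_seed(spec$seed, "miss"))
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$table), " patients, ",
      ncol(x$table), " columns; pCR ",
      sum(x$table$outcome == "pCR"), "/", nrow(x$table),
      "; Bayes AUC ", round(x$truth$bayes_auc, 3), "\n", sep = "")
  invisible(x)
}

# modality tag for every column of the generated table
cohort_modalities <- function(cols, radiomic_cols) {
  tag <- dplyr::case_when(
    cols %in% c("patient_id", "outcome", "batch",
                "efs_time", "efs_event") ~ "meta",
    cols %in% c("age", "family_history", "contraception",
                "clinical_t_stage", "clinical_n_stage", "multifocal",
                "regimen") ~ "clinical",
    cols %in% c("histological_type", "histological_grade",
                "mitosis_count", "ki67_ihc") ~ "histopathological",
    cols %in% c("cdc2", "cdc20", "kpna2", "mybl2", "ggir",
                "ki67_mrna", "tp53_status") ~ "genomic",
    cols %in% c("tumor_suvmax", "node_suvmax", "mtv") ~ "pet",
    cols %in% radiomic_cols ~ "radiomic",
    TRUE ~ NA_character_
  )
  tibble(column = cols, modality = tag)
}

# censoring window c_max such that P(C < T) = target for C ~ U(0, c_max)
# and T exponential with the cohort's mixture of rates
censor_window <- function(rates, target) {
  # P(C < T) = mean over rates of (1 - exp(-lambda u)) / (lambda u),
  # monotone decreasing in u (u -> 0: always censored; u -> Inf: never)
  p_cens <- function(u) mean((1 - exp(-rates * u)) / (rates * u))
  if (target <= 0) return(1e9)
  uniroot(function(u) p_cens(u) - target, c(1e-3, 1e6), tol = 1e-8)$root
}

#' Mask values completely at random, column by column
#'
#' Outcome, batch and survival columns are never masked.
#'
#' @param table A cohort tibble.
#' @param rates Named per-column missing fractions in [0, 1).
#' @param seed Integer seed; the same seed reproduces the same mask.
#' @return The table with `NA`s injected.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(seed = 1))
#' tab <- inject_missingness(coh$table, c(age = 0.1), seed = 2)
inject_missingness <- function(table, rates, seed = 1L) {
  assert_that(all(rates >= 0), "rates must be >= 0")
  if (any(rates >= 1)) abort("missingness rate >= 1 is not allowed")
  protected <- c("patient_id", "outcome", "batch", "efs_time", "efs_event")
  bad <- intersect(names(rates), protected)
  if (length(bad))
    abort(paste("cannot mask protected column(s):",
                paste(bad, collapse = ", ")))
  missing_cols <- setdiff(names(rates), names(table))
  if (length(missing_cols))
    abort(paste("unknown column(s):", paste(missing_cols, collapse = ", ")))
  with_seed(seed, {
    for (cl in names(rates)) {
      if (rates[[cl]] == 0) next
      mask <- runif(nrow(table)) < rates[[cl]]
      table[[cl]][mask] <- NA
    }
  })
  table
}

#' Write / read a cohort table as CSV plus a YAML metadata sidecar
#'
#' The sidecar records modality tags per column and the generating seed,
#' so a round-tripped table keeps its modality structure.
#'
#' @param cohort A `synthetic_cohort` (or a list with `table` and
#'   `modalities`).
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.yaml`.
#' @return `write_cohort()` the path, invisibly; `read_cohort()` a list
#'   with `table` and `modalities`.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort$table, path, na = "")
  meta <- list(
    modalities = setNames(as.list(cohort$modalities$modality),
                          cohort$modalities$column),
    seed = if (!is.null(cohort$spec)) cohort$spec$seed else NA
  )
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  table <- readr::read_csv(path, show_col_types = FALSE,
                           na = c("", "NA"))
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  list(table = table,
       modalities = tibble(column = names(meta$modalities),
                           modality = unname(unlist(meta$modalities))),
       seed = meta$seed)
}
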