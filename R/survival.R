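#' Kaplan-Meier estimate of event-free survival
#'
#' Product-limit estimator: at each distinct event time the survival
#' curve steps down by the fraction of the risk set experiencing an
#' event; censored times reduce the risk set without a step.
#'
#' @param time Nonnegative follow-up times (e.g. months from surgery).
#' @param event 0/1 (or logical) event indicator.
#' @param group Optional group labels for stratified curves.
#' @return A `km_estimate` tibble: `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`.
#' @export
#' @examples
#' km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
#' km$survival  # 0.75 0.50 0.25 0.00
km_estimate <- function(time, event, group = NULL) {
  assert_that(all(time >= 0), "survival times must be nonnegative")
  assert_that(all(event %in% c(0, 1)), "event indicator must be 0/1")
  if (is.null(group)) group <- rep("all", length(time))
  assert_that(length(time) == length(event) &&
                length(time) == length(group),
              "time, event and group must have equal length")
  fit <- survival::survfit(
    survival::Surv(time, event) ~ g,
    data = data.frame(time = time, event = as.numeric(event),
                      g = as.character(group)))
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) unique(as.character(group)) else
    sub("^g=", "", as.character(sm$strata))
  out <- tibble(group = grp, time = sm$time, n_risk = sm$n.risk,
                n_event = sm$n.event, n_censor = sm$n.censor,
                survival = sm$surv)
  class(out) <- c("km_estimate", class(out))
  out
}

#' Log-rank test comparing event-free survival between two groups
#'
#' Standard observed-minus-expected statistic over the pooled event
#' times, with the two-sided p-value from a chi-square distribution
#' with one degree of freedom.
#'
#' @param time Nonnegative follow-up times.
#' @param event 0/1 event indicator.
#' @param group Two-level group labels (e.g. predicted pCR vs non-pCR).
#' @return Tibble with `statistic`, `df`, `p_value` and per-group
#'   observed/expected event counts in `observed`/`expected` list
#'   columns.
#' @export
#' @examples
#' logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("a", "a", "b", "b"))
logrank_test <- function(time, event, group) {
  assert_that(all(time >= 0), "survival times must be nonnegative")
  group <- as.character(group)
  lv <- unique(group)
  assert_that(length(lv) == 2, "exactly two nonempty groups required")
  if (sum(event) == 0) {
    warn("no events in either group: p = 1 by convention")
    return(tibble(statistic = 0, df = 1L, p_value = 1,
                  observed = list(setNames(c(0, 0), lv)),
                  expected = list(setNames(c(0, 0), lv))))
  }
  sd <- survival::survdiff(
    survival::Surv(time, event) ~ g,
    data = data.frame(time = time, event = as.numeric(event), g = group))
  tibble(statistic = unname(sd$chisq), df = 1L,
         p_value = pchisq(sd$chisq, 1, lower.tail = FALSE),
         observed = list(setNames(as.numeric(sd$obs),
                                  sub("^g=", "", names(sd$n)))),
         expected = list(setNames(as.numeric(sd$exp),
                                  sub("^g=", "", names(sd$n)))))
}
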