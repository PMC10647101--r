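#' Kaplan-Meier estimate with Greenwood variance
#'
#' Product-limit estimator of the survival function, as a tidy step-function
#' table. Computation is delegated to [survival::survfit()]; the returned
#' standard error is Greenwood's estimate on the survival scale.
#'
#' @param times Nonnegative follow-up times (months).
#' @param events Logical event indicators (FALSE = censored).
#' @return A tibble with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`, `std_err`, `ci_low`, `ci_high`, right-continuous in `time`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) {
    abort("empty input", class = "endomol_survival_error")
  }
  stopifnot(length(times) == length(events), all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                           conf.type = "log-log")
  tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         n_censor = fit$n.censor, surv = fit$surv,
         # Greenwood SE on the survival scale (0 once the curve reaches 0)
         std_err = ifelse(fit$surv == 0, 0, fit$std.err * fit$surv),
         ci_low = fit$lower, ci_high = fit$upper)
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected statistic over the pooled event times,
#' with `k - 1` degrees of freedom for `k` groups, via
#' [survival::survdiff()].
#'
#' @param times Follow-up times.
#' @param events Logical event indicators.
#' @param group Group labels (at least two non-empty groups).
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  if (any(table(group) == 0)) {
    abort("empty group in log-rank test", class = "endomol_survival_error")
  }
  if (nlevels(group) < 2) {
    abort("log-rank test needs at least two non-empty groups",
          class = "endomol_survival_error")
  }
  fit <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ group)
  df <- length(fit$n) - 1
  tibble(statistic = fit$chisq, df = df,
         p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}
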