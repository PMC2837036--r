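#' Kaplan-Meier curve for one group
#'
#' Product-limit estimator over one group of a survival table (deaths at tied
#' times are processed before censorings, the standard convention of the
#' underlying estimator).
#'
#' @param table A [survival_table()].
#' @param group Group label.
#' @return List of class `KmCurve`: `group`, `time` (event-time grid), `surv`,
#'   `n_risk`, `n_event`, `n_censor`, `n`.
#' @export
kaplan_meier <- function(table, group) {
  rec <- table[table$group == group, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no records in group ", group)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = rec)
  structure(list(group = group, time = fit$time, surv = fit$surv,
                 n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor, n = nrow(rec)),
            class = "KmCurve")
}

#' Survival rate at named horizons
#'
#' Reads the product-limit curve at each horizon: the estimate after the last
#' observed time not exceeding the horizon (1 before the first).
#'
#' @param curve A [kaplan_meier()] curve.
#' @param horizons Numeric vector of times (years).
#' @return Named numeric vector of survival probabilities.
#' @export
km_rate_at <- function(curve, horizons) {
  vapply(horizons, function(h) {
    idx <- which(curve$time <= h)
    if (length(idx) == 0L) 1 else curve$surv[max(idx)]
  }, numeric(1)) -> out
  names(out) <- paste0("t", horizons)
  out
}

#' Log-rank test between two groups
#'
#' Standard one-degree-of-freedom log-rank statistic: observed versus expected
#' events summed over the distinct event times with hypergeometric variance,
#' chi-square reference. With zero events in both groups the test is
#' undefined; `p = 1` is returned with a warning.
#'
#' @param table A [survival_table()].
#' @param group_a,group_b Group labels.
#' @return List with `chi_square`, `p`, `n` (per group), `observed`,
#'   `expected`.
#' @export
logrank <- function(table, group_a, group_b) {
  rec <- table[table$group %in% c(group_a, group_b), , drop = FALSE]
  if (!all(c(group_a, group_b) %in% rec$group))
    stop("both groups must be non-empty")
  if (sum(rec$event) == 0L) {
    warning("no events in either group; log-rank undefined, p = 1")
    return(list(chi_square = 0, p = 1,
                n = table(factor(rec$group, levels = c(group_a, group_b))),
                observed = c(0, 0), expected = c(0, 0)))
  }
  rec$group <- factor(rec$group, levels = c(group_a, group_b))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = rec)
  list(chi_square = sd$chisq,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n = sd$n, observed = sd$obs, expected = sd$exp)
}
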