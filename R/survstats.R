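#' Linear regression of overall survival on a continuous metric
#'
#' Ordinary least squares of survival days on the predictor, reported as the
#' slope (days per metric unit), its t-based 95% confidence interval and
#' two-sided p-value. This mirrors a univariate outcome screen over
#' tract-derived metrics; censoring is ignored by design (the companion
#' Kaplan-Meier/log-rank path handles it).
#'
#' @param os_days numeric survival times.
#' @param x numeric predictor.
#' @return `regression_result`: list with `beta`, `ci95`, `p_value`,
#'   `intercept`, `n`.
#' @export
ols_survival <- function(os_days, x) {
  stopifnot(length(os_days) == length(x))
  if (length(x) < 3) stopf("need n >= 3")
  if (stats::sd(x) == 0) stopf("predictor is constant")
  fit <- stats::lm(os_days ~ x)
  sm <- summary(fit)
  ci <- stats::confint(fit)["x", ]
  structure(list(beta = unname(stats::coef(fit)["x"]),
                 ci95 = unname(ci),
                 p_value = sm$coefficients["x", "Pr(>|t|)"],
                 intercept = unname(stats::coef(fit)[1]),
                 n = length(x)),
            class = "regression_result")
}

#' Welch two-sided t-test of survival means between binary strata
#'
#' Unequal-variance statistic with Satterthwaite degrees of freedom; the
#' degenerate zero-variance case is handled directly with a df floor of 1.
#' @param a,b numeric vectors (each n >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
welch_ttest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stopf("each group needs n >= 2")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    t <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    return(list(t = t, df = 1,
                p = if (t == 0) 1 else 0))
  }
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
  df <- max(df, 1)
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Quartile stratification of a predictor
#'
#' Cut points at the 25/50/75 sample percentiles (type-7, linear
#' interpolation); values tied with a cut point fall to the lower group.
#' @param values numeric (n >= 4).
#' @param type quantile type passed to [stats::quantile()].
#' @return factor with levels Q1-Q4.
#' @export
quartile_groups <- function(values, type = 7) {
  if (length(values) < 4) stopf("need n >= 4 for quartiles")
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75), type = type,
                        names = FALSE)
  if (length(unique(values)) == 1) {
    warning("all values equal; every subject assigned Q1")
    return(factor(rep("Q1", length(values)), levels = paste0("Q", 1:4)))
  }
  breaks <- unique(c(-Inf, qs, Inf))
  lab <- paste0("Q", seq_len(length(breaks) - 1))
  out <- cut(values, breaks = breaks, labels = lab, right = TRUE)
  factor(as.character(out), levels = paste0("Q", 1:4))
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-censored survival curve; subjects censored at an event time remain
#' at risk for that event time.
#' @param times positive survival days.
#' @param events logical, TRUE = death observed.
#' @return `km_curve`: data.frame with `time` (distinct event times),
#'   `n_risk`, `n_event`, `survival`; attribute `fit` holds the underlying
#'   [survival::survfit] object.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events))
  if (any(times <= 0)) stopf("survival times must be positive")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  sm <- summary(fit, censored = FALSE)
  keep <- sm$n.event > 0
  out <- data.frame(time = sm$time[keep], n_risk = sm$n.risk[keep],
                    n_event = sm$n.event[keep], survival = sm$surv[keep])
  attr(out, "fit") <- fit
  class(out) <- c("km_curve", "data.frame")
  out
}

#' K-sample log-rank test
#'
#' Standard hypergeometric-increment log-rank chi-square with `k - 1`
#' degrees of freedom (no ties correction beyond multi-event handling at
#' tied times).
#' @param groups list of `list(times =, events =)` per group, or a
#'   data.frame with columns `times`, `events`, `group`.
#' @return list with `chi2`, `df`, `p`.
#' @export
logrank_test <- function(groups) {
  if (is.data.frame(groups)) {
    df <- groups
    stopifnot(all(c("times", "events", "group") %in% names(df)))
  } else {
    if (length(groups) < 2) stopf("need >= 2 groups")
    sizes <- vapply(groups, function(g) length(g$times), integer(1))
    if (any(sizes == 0)) stopf("a group has zero subjects")
    df <- data.frame(
      times = unlist(lapply(groups, `[[`, "times")),
      events = unlist(lapply(groups, `[[`, "events")),
      group = rep(seq_along(groups), sizes))
  }
  df$group <- factor(df$group)
  if (nlevels(df$group) < 2) stopf("need >= 2 groups")
  if (any(table(df$group) == 0)) stopf("a group has zero subjects")
  if (sum(df$events) < 1) stopf("need >= 1 event")
  sd_ <- survival::survdiff(
    survival::Surv(times, events) ~ group, data = df)
  k <- nlevels(droplevels(df$group))
  chi2 <- sd_$chisq
  dfree <- k - 1
  list(chi2 = unname(chi2), df = dfree,
       p = stats::pchisq(chi2, dfree, lower.tail = FALSE))
}

#' Quartile-stratified survival analysis of a cohort metric
#'
#' Convenience wrapper reproducing the outcome workflow for one predictor:
#' quartile groups, per-quartile KM curves, the k-sample log-rank test, and
#' the univariate OLS regression.
#' @param cohort a `cohort_table`.
#' @param metric column name.
#' @return list with `quartiles`, `km` (per-quartile `km_curve`s),
#'   `logrank`, `ols`.
#' @export
survival_by_quartile <- function(cohort, metric) {
  stopifnot(metric %in% names(cohort))
  q <- quartile_groups(cohort[[metric]])
  km <- lapply(split(seq_len(nrow(cohort)), q), function(i)
    km_estimate(cohort$os_days[i], cohort$event[i]))
  lr <- logrank_test(data.frame(times = cohort$os_days,
                                events = cohort$event, group = q))
  list(quartiles = q, km = km, logrank = lr,
       ols = ols_survival(cohort$os_days, cohort[[metric]]))
}
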