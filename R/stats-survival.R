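# Survival machinery for the trial analyses: Kaplan-Meier summaries,
# stratified log-rank comparison, and stratified Cox hazard ratios with
# 90% Wald intervals. Estimation is delegated to the survival package;
# this layer fixes the conventions (median definition, CI level, Efron
# ties) used throughout the analyses.

#' Kaplan-Meier estimate for one group
#'
#' Product-limit estimator; the median is the smallest observed time at
#' which the survival curve is at or below 0.5, and is reported as
#' \code{NA} (not reached) when the curve never gets there.
#'
#' @param times nonnegative event/censoring times (months).
#' @param events logical or 0/1 event indicators.
#' @return object of class \code{km_fit}: \code{time}, \code{surv},
#'   \code{n_risk}, \code{n_event}, \code{median}, and \code{surv_at(t)},
#'   a right-continuous step function returning S(t).
#' @export
km_estimate <- function(times, events) {
  if (length(times) < 1) stop("need at least one subject")
  if (any(times < 0)) stop("negative times are not allowed")
  events <- as.integer(as.logical(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  s <- summary(fit, censored = TRUE)
  med_idx <- which(fit$surv <= 0.5)
  med <- if (length(med_idx) == 0) NA_real_ else fit$time[min(med_idx)]
  step <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  structure(
    list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
         n_event = fit$n.event, median = med, n = length(times),
         surv_at = step),
    class = "km_fit"
  )
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier fit: n = %d, events = %d, median = %s\n",
              x$n, sum(x$n_event),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

.as_strata <- function(stratum, n) {
  if (is.null(stratum)) factor(rep("all", n)) else factor(stratum)
}

#' Stratified log-rank test
#'
#' Observed-minus-expected event counts and hypergeometric variances are
#' accumulated within each stratum and pooled into a one-degree-of-freedom
#' chi-square. With a single stratum this reduces to the ordinary log-rank
#' test.
#'
#' @param times,events survival times and event indicators.
#' @param group two-level group label.
#' @param stratum optional stratification factor (e.g. ECOG x prior
#'   adjuvant therapy cell).
#' @return list with \code{chisq}, \code{df} (1) and \code{p.value}.
#' @export
stratified_logrank <- function(times, events, group, stratum = NULL) {
  group <- factor(group)
  if (nlevels(droplevels(group)) != 2) {
    stop("group must have exactly two represented levels")
  }
  strata_f <- .as_strata(stratum, length(times))
  events <- as.integer(as.logical(events))
  sd <- survival::survdiff(
    survival::Surv(times, events) ~ group + survival::strata(strata_f)
  )
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(chisq = unname(sd$chisq), df = 1L, p.value = p)
}

#' Stratified Cox model for a two-group comparison
#'
#' Maximizes the stratified partial likelihood for a single binary group
#' covariate (Efron tie handling by default) and reports the hazard ratio
#' with a Wald confidence interval on the log scale, alongside per-group
#' Kaplan-Meier medians and the stratified log-rank p-value. The hazard
#' ratio is for the first factor level's hazard relative to the
#' reference; set \code{group} as a factor to control the direction.
#'
#' @param times,events survival times and event indicators.
#' @param group two-level group label; the returned HR multiplies the
#'   hazard of the second level relative to the first.
#' @param stratum optional stratification factor.
#' @param ci_level confidence level (default 0.90, the trial's reporting
#'   convention).
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @return object of class \code{survival_comparison}: \code{hr},
#'   \code{ci} (named lower/upper), \code{coef}, \code{se},
#'   \code{logrank_p}, \code{median_by_group}, \code{n_by_group},
#'   \code{events_by_group}, \code{ci_level}.
#' @export
stratified_cox <- function(times, events, group, stratum = NULL,
                           ci_level = 0.90, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  group <- droplevels(factor(group))
  if (nlevels(group) != 2) stop("group must have exactly two represented levels")
  strata_f <- .as_strata(stratum, length(times))
  events <- as.integer(as.logical(events))
  fit <- survival::coxph(
    survival::Surv(times, events) ~ group + survival::strata(strata_f),
    ties = ties
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (is.na(beta) || !is.finite(beta) || abs(beta) > 15 || se > 100) {
    stop("partial likelihood is monotone (complete separation); ",
         "hazard ratio is not estimable")
  }
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  ci <- exp(beta + c(-1, 1) * z * se)
  med <- vapply(levels(group), function(g) {
    km_estimate(times[group == g], events[group == g])$median
  }, numeric(1))
  lr <- stratified_logrank(times, events, group, stratum)
  structure(
    list(hr = exp(beta), ci = c(lower = ci[1], upper = ci[2]),
         coef = beta, se = se, logrank_p = lr$p.value,
         median_by_group = med,
         n_by_group = table(group),
         events_by_group = tapply(events, group, sum),
         ci_level = ci_level, ties = ties,
         comparison = paste(levels(group)[2], "vs", levels(group)[1])),
    class = "survival_comparison"
  )
}

#' @export
print.survival_comparison <- function(x, ...) {
  med <- vapply(x$median_by_group, function(m)
    if (is.na(m)) "NR" else sprintf("%.1f", m), character(1))
  cat(sprintf("Survival comparison (%s)\n", x$comparison))
  cat(sprintf("  medians  : %s\n",
              paste(sprintf("%s = %s mo", names(x$median_by_group), med),
                    collapse = ", ")))
  cat(sprintf("  HR       : %.2f (%d%% CI %.2f-%.2f)\n",
              x$hr, round(100 * x$ci_level), x$ci["lower"], x$ci["upper"]))
  cat(sprintf("  log-rank : p = %.2g\n", x$logrank_p))
  invisible(x)
}

#' Wald test for an arm-by-marker interaction in a Cox model
#'
#' Fits an unstratified Cox model with both main effects and their
#' product term and returns the Wald p-value for the interaction
#' coefficient. Used for the treatment-by-KRAS predictiveness check.
#'
#' @param times,events survival times and event indicators.
#' @param group,marker two-level factors.
#' @return list with \code{interaction_coef} and \code{p.value}.
#' @export
cox_interaction_p <- function(times, events, group, marker) {
  group <- droplevels(factor(group))
  marker <- droplevels(factor(marker))
  events <- as.integer(as.logical(events))
  fit <- survival::coxph(survival::Surv(times, events) ~ group * marker)
  sm <- summary(fit)$coefficients
  idx <- grep(":", rownames(sm))
  list(interaction_coef = unname(sm[idx, "coef"]),
       p.value = unname(sm[idx, "Pr(>|z|)"]))
}
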