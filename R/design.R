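# Trial design arithmetic: Schoenfeld event counts, the exponential
# median projection, and empirical power by simulation of event-driven
# log-rank analyses.

#' Required number of events (Schoenfeld formula)
#'
#' Number of deaths required for a two-arm log-rank test to detect a
#' hazard-ratio alternative:
#' \deqn{d = \lceil (z_{1-\alpha/2} + z_{1-\beta})^2 / (p_1 p_2 (\log HR)^2) \rceil}
#' where \eqn{p_1, p_2} are the allocation fractions.
#'
#' @param alpha two-sided significance level (default 0.10).
#' @param power target power (default 0.80).
#' @param hr hazard-ratio alternative (default 0.65); must differ from 1.
#' @param allocation integer allocation ratio, e.g. \code{c(2, 1)}.
#' @return required event count (integer).
#' @export
#' @examples
#' schoenfeld_events()  # 150 deaths for the default design
schoenfeld_events <- function(alpha = 0.10, power = 0.80, hr = 0.65,
                              allocation = c(2, 1)) {
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie in (0, 1)")
  }
  if (hr <= 0) stop("hr must be positive")
  if (hr == 1) stop("undetectable alternative: hr must differ from 1")
  p1 <- allocation[1] / sum(allocation)
  p2 <- allocation[2] / sum(allocation)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  as.integer(ceiling(z^2 / (p1 * p2 * log(hr)^2)))
}

#' Median survival projected under a hazard ratio
#'
#' Under exponential proportional hazards, scaling the hazard by HR
#' scales the median by 1/HR; reported to one decimal, the trial's
#' convention for medians in months.
#'
#' @param control_median control-arm median survival (months).
#' @param hr hazard ratio (experimental vs control).
#' @return projected experimental-arm median (months, one decimal).
#' @export
#' @examples
#' projected_median(8.5, 0.65)  # 13.1
projected_median <- function(control_median, hr) {
  if (control_median <= 0 || hr <= 0) stop("inputs must be positive")
  round(control_median / hr, 1)
}

#' Empirical power of an event-driven log-rank analysis
#'
#' Simulates two-arm trials with exponential survival (control median
#' \code{control_median}, hazard ratio \code{hr} in the experimental
#' arm), uniform accrual, and analysis triggered when
#' \code{events_required} deaths have occurred; each trial is tested with
#' a two-sided log-rank test at level \code{alpha}.
#'
#' @param n_patients patients per trial (default 225 with 2:1 allocation,
#'   enough to reach the default 150 events).
#' @param n_reps number of simulated trials (at least 100).
#' @param alpha two-sided level (default 0.10).
#' @param hr hazard ratio, experimental vs control (default 0.65; 1 gives
#'   the null calibration).
#' @param control_median control-arm median survival in months.
#' @param allocation allocation ratio, experimental first.
#' @param events_required deaths triggering the analysis (default the
#'   Schoenfeld count for the design, except under the null where no
#'   alternative exists and 150 is used).
#' @param accrual_months uniform accrual window (months).
#' @param seed optional RNG seed.
#' @return list with \code{power} (rejection fraction), \code{se}
#'   (binomial standard error), \code{n_reps}, \code{events_required}.
#' @export
power_by_simulation <- function(n_patients = 225, n_reps = 2000,
                                alpha = 0.10, hr = 0.65,
                                control_median = 8.5,
                                allocation = c(2, 1),
                                events_required = NULL,
                                accrual_months = 23, seed = NULL) {
  if (n_reps < 100) stop("n_reps must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(events_required)) {
    events_required <- if (hr == 1) 150L else
      schoenfeld_events(alpha = alpha, power = 0.80, hr = hr,
                        allocation = allocation)
  }
  if (n_patients < events_required) {
    stop("n_patients must be at least events_required")
  }
  n_exp <- round(n_patients * allocation[1] / sum(allocation))
  arm <- factor(rep(c("experimental", "control"),
                    c(n_exp, n_patients - n_exp)))
  rate0 <- log(2) / control_median
  rates <- ifelse(arm == "experimental", rate0 * hr, rate0)
  rejections <- vapply(seq_len(n_reps), function(i) {
    entry <- stats::runif(n_patients, 0, accrual_months)
    t_raw <- stats::rexp(n_patients, rates)
    calendar <- entry + t_raw
    cutoff <- sort(calendar)[events_required]
    obs <- pmin(t_raw, pmax(cutoff - entry, 0))
    evt <- as.integer(calendar <= cutoff)
    sd <- survival::survdiff(survival::Surv(obs, evt) ~ arm)
    stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE) < alpha
  }, logical(1))
  pw <- mean(rejections)
  list(power = pw, se = sqrt(pw * (1 - pw) / n_reps),
       n_reps = n_reps, events_required = events_required)
}
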