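# Categorical endpoint machinery: Cochran-Mantel-Haenszel response
# comparison, Fisher exact tests for adverse events and QoL
# deterioration, Wilcoxon rank-sum, and the RECIST response-rate
# summaries.

#' Cochran-Mantel-Haenszel test and pooled odds ratio for 2x2xK tables
#'
#' Computes the Mantel-Haenszel pooled odds ratio with a
#' Robins-Breslow-Greenland confidence interval and the CMH chi-square
#' test (no continuity correction). With a single stratum the pooled
#' odds ratio equals the simple cross-product ratio.
#'
#' @param tables a 2x2 matrix (one stratum) or a 2x2xK array; rows are
#'   groups, columns are outcome (success, failure).
#' @param ci_level confidence level for the odds ratio (default 0.90).
#' @return list with \code{or} (Mantel-Haenszel pooled odds ratio),
#'   \code{ci}, \code{chisq}, \code{p.value}, \code{k} strata.
#' @export
cmh_response_test <- function(tables, ci_level = 0.90) {
  if (is.matrix(tables)) tables <- array(tables, dim = c(dim(tables), 1))
  if (length(dim(tables)) != 3 || any(dim(tables)[1:2] != 2)) {
    stop("tables must be 2x2 or 2x2xK")
  }
  if (any(tables < 0)) stop("counts must be nonnegative")
  if (sum(tables) == 0) stop("all-zero table")
  k <- dim(tables)[3]
  a <- tables[1, 1, ]; b <- tables[1, 2, ]
  c_ <- tables[2, 1, ]; d <- tables[2, 2, ]
  n <- a + b + c_ + d
  use <- n > 0
  a <- a[use]; b <- b[use]; c_ <- c_[use]; d <- d[use]; n <- n[use]

  # CMH chi-square: pooled hypergeometric observed-minus-expected
  e <- (a + b) * (a + c_) / n
  v <- (a + b) * (c_ + d) * (a + c_) * (b + d) / (n^2 * pmax(n - 1, 1))
  chisq <- sum(a - e)^2 / sum(v)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)

  # Mantel-Haenszel pooled OR with RBG variance for the log OR
  R <- a * d / n
  S <- b * c_ / n
  or <- sum(R) / sum(S)
  P <- (a + d) / n
  Q <- (b + c_) / n
  var_log <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * sqrt(var_log))
  list(or = or, ci = c(lower = ci[1], upper = ci[2]),
       chisq = chisq, p.value = p, k = sum(use), ci_level = ci_level)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric two-sided p-value using the minimum-likelihood
#' convention: the sum of probabilities of all tables at least as extreme
#' (point probability no larger) than the observed one.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be nonnegative integers")
  }
  stats::fisher.test(table)$p.value
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Uses the exact null distribution when the combined sample size is at
#' most 12 and there are no ties; otherwise the normal approximation with
#' tie correction and continuity correction.
#'
#' @param x,y numeric samples, both nonempty.
#' @return list with \code{p.value}, \code{statistic} (Mann-Whitney W for
#'   x), and \code{exact} (whether the exact branch was used).
#' @export
wilcoxon_ranksum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  list(p.value = wt$p.value, statistic = unname(wt$statistic), exact = exact)
}

#' Quality-of-life deterioration rule
#'
#' Deterioration is a change score from baseline of -10 points or lower
#' on the 0-100 instrument scale.
#'
#' @param baseline,followup scores on the 0-100 scale.
#' @return logical vector.
#' @export
qol_deterioration <- function(baseline, followup) {
  (followup - baseline) <= -10
}

#' Objective response and disease control rates
#'
#' ORR is the proportion of randomized patients with a complete or
#' partial response; DCR additionally counts stable disease.
#' Not-evaluable (NE) patients stay in the denominator.
#'
#' @param responses character vector of best RECIST responses, each one
#'   of CR, PR, SD, PD, NE.
#' @return list with \code{orr}, \code{dcr}, \code{n}, and the response
#'   count table.
#' @export
orr_dcr <- function(responses) {
  if (length(responses) == 0) stop("empty arm")
  allowed <- c("CR", "PR", "SD", "PD", "NE")
  if (!all(responses %in% allowed)) {
    stop("responses must be one of ", paste(allowed, collapse = ", "))
  }
  n <- length(responses)
  counts <- table(factor(responses, levels = allowed))
  list(
    orr = sum(counts[c("CR", "PR")]) / n,
    dcr = sum(counts[c("CR", "PR", "SD")]) / n,
    n = n,
    counts = counts
  )
}
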