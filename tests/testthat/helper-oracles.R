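# Fixture constructors and brute-force oracles, independent of the
# package's implementation paths.

make_variant <- function(sample_id = "S1", chrom = "12", pos = 100,
                         ref = "A", alt = "T", gene = "KRAS",
                         effect = "missense", is_snv = NULL,
                         is_coding = TRUE, allele_fraction = 0.1,
                         origin = "somatic", cna_flag = FALSE) {
  if (is.null(is_snv)) is_snv <- nchar(ref) == 1 && nchar(alt) == 1
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, gene = gene, effect = effect, is_snv = is_snv,
             is_coding = is_coding, allele_fraction = allele_fraction,
             origin = origin, cna_flag = cna_flag,
             stringsAsFactors = FALSE)
}

make_variants <- function(...) do.call(rbind, list(...))

# Exact two-sided Fisher p by full enumeration over the hypergeometric
# support (minimum-likelihood convention).
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(support, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided rank-sum p by enumerating all assignments of the
# combined ranks to x (requires no ties).
ranksum_enum_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2  # Mann-Whitney U for x
  combos <- utils::combn(m + n, m)
  u_all <- apply(combos, 2, function(ix) sum(seq_len(m + n)[ix]) - m * (m + 1) / 2)
  p_lo <- mean(u_all <= w_obs)
  p_hi <- mean(u_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Stratified Cox log partial likelihood for a single binary covariate,
# written out directly (no ties assumed in the data used with it).
cox_loglik_oracle <- function(beta, time, event, x, stratum = NULL) {
  if (is.null(stratum)) stratum <- rep(1, length(time))
  ll <- 0
  for (s in unique(stratum)) {
    sel <- stratum == s
    t_s <- time[sel]; e_s <- event[sel]; x_s <- x[sel]
    for (i in which(e_s == 1)) {
      risk <- t_s >= t_s[i]
      ll <- ll + beta * x_s[i] - log(sum(exp(beta * x_s[risk])))
    }
  }
  ll
}

# 1-D maximizer of the written-out partial likelihood.
cox_grid_oracle <- function(time, event, x, stratum = NULL,
                            lower = -5, upper = 5) {
  opt <- stats::optimize(function(b) -cox_loglik_oracle(b, time, event, x, stratum),
                         c(lower, upper), tol = 1e-9)
  opt$minimum
}

# Naive recount of the calibration trajectory with explicit loops.
calibration_naive_oracle <- function(ctf, kras_status) {
  thresholds <- sort(unique(ctf))
  out <- data.frame(threshold = thresholds, n_retained = NA_integer_,
                    wt_frequency = NA_real_)
  for (i in seq_along(thresholds)) {
    kept_wt <- 0; kept <- 0
    for (j in seq_along(ctf)) {
      if (ctf[j] >= thresholds[i]) {
        kept <- kept + 1
        if (kras_status[j] == "wildtype") kept_wt <- kept_wt + 1
      }
    }
    out$n_retained[i] <- kept
    out$wt_frequency[i] <- kept_wt / kept
  }
  out
}

# Hand product-limit estimator (no package calls).
km_oracle <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (k in seq_along(ut)) {
    at_risk <- sum(times >= ut[k])
    d <- sum(times == ut[k] & events == 1)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  list(time = ut, surv = surv)
}
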