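# Prevalence-targeted CTF threshold calibration: iteratively raise the
# circulating-tumor-fraction cutoff, dropping putative low-shedding
# samples, until the KRAS-wildtype frequency falls to an expected
# population ceiling while retaining an acceptable fraction of samples.

#' Apply a CTF threshold
#'
#' Samples with CTF values less than the threshold are excluded; ties at
#' the threshold are retained.
#'
#' @param ctf numeric vector of per-sample CTF values.
#' @param threshold CTF cutoff.
#' @return logical vector, TRUE for retained samples.
#' @export
apply_ctf_threshold <- function(ctf, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1) {
    stop("threshold must be a single number")
  }
  !is.na(ctf) & ctf >= threshold
}

#' Calibrate a CTF threshold against an expected KRAS-wildtype prevalence
#'
#' Scans the ascending distinct observed CTF values as candidate
#' thresholds. At each candidate, samples below the threshold are dropped
#' and the KRAS-wildtype frequency among retained samples is recomputed.
#' The chosen threshold is the smallest candidate at which the wildtype
#' frequency is at or below \code{target_ceiling} while the retained
#' fraction stays at or above \code{retention_floor}.
#'
#' Samples with missing CTF cannot be placed relative to any threshold;
#' they are excluded from calibration and reported in
#' \code{excluded_missing_ctf}.
#'
#' @param metrics data.frame with columns \code{sample_id}, \code{ctf},
#'   \code{kras_status}.
#' @param target_ceiling upper bound for the filtered wildtype frequency
#'   (default 0.13, just above the ~10\% wildtype prevalence expected in
#'   pancreatic ductal adenocarcinoma).
#' @param retention_floor minimum fraction of (non-missing) samples that
#'   must survive the filter (default 0.5).
#' @return an object of class \code{ctf_calibration}: chosen threshold,
#'   retained sample ids, wildtype frequency at the threshold, the full
#'   trajectory (threshold, n_retained, wt_frequency, retained_fraction),
#'   and the configuration used.
#' @export
calibrate_ctf_threshold <- function(metrics, target_ceiling = 0.13,
                                    retention_floor = 0.5) {
  for (col in c("sample_id", "ctf", "kras_status")) {
    if (!col %in% names(metrics)) stop("metrics table is missing column: ", col)
  }
  if (!is.numeric(target_ceiling) || target_ceiling <= 0 || target_ceiling >= 1) {
    stop("target_ceiling must lie in (0, 1)")
  }
  if (!is.numeric(retention_floor) || retention_floor < 0 || retention_floor >= 1) {
    stop("retention_floor must lie in [0, 1)")
  }
  missing_ctf <- metrics$sample_id[is.na(metrics$ctf)]
  m <- metrics[!is.na(metrics$ctf), , drop = FALSE]
  if (nrow(m) == 0) stop("no samples with a non-missing CTF")
  is_wt <- m$kras_status == "wildtype"
  if (all(is_wt)) stop("degenerate: all samples are KRAS wildtype")

  n_total <- nrow(m)
  candidates <- sort(unique(m$ctf))
  trajectory <- data.frame(
    threshold = candidates,
    n_retained = NA_integer_,
    wt_frequency = NA_real_,
    retained_fraction = NA_real_
  )
  chosen <- NA_real_
  for (i in seq_along(candidates)) {
    keep <- apply_ctf_threshold(m$ctf, candidates[i])
    n_ret <- sum(keep)
    wt_freq <- sum(is_wt & keep) / n_ret
    trajectory$n_retained[i] <- n_ret
    trajectory$wt_frequency[i] <- wt_freq
    trajectory$retained_fraction[i] <- n_ret / n_total
    if (is.na(chosen) && wt_freq <= target_ceiling &&
        n_ret / n_total >= retention_floor) {
      chosen <- candidates[i]
    }
  }
  if (is.na(chosen)) {
    stop("no qualifying threshold: wildtype frequency never reached ",
         "the target ceiling while retention stayed above the floor")
  }
  keep <- apply_ctf_threshold(m$ctf, chosen)
  structure(
    list(
      chosen_threshold = chosen,
      retained_ids = m$sample_id[keep],
      wt_frequency_at_threshold = sum(is_wt & keep) / sum(keep),
      trajectory = trajectory,
      target_ceiling = target_ceiling,
      retention_floor = retention_floor,
      excluded_missing_ctf = as.character(missing_ctf),
      n_calibration = n_total
    ),
    class = "ctf_calibration"
  )
}

#' @export
print.ctf_calibration <- function(x, ...) {
  cat("CTF threshold calibration\n")
  cat(sprintf("  chosen threshold : %.4g (CTF = %.2f%%)\n",
              x$chosen_threshold, 100 * x$chosen_threshold))
  cat(sprintf("  retained samples : %d / %d (%.1f%%)\n",
              length(x$retained_ids), x$n_calibration,
              100 * length(x$retained_ids) / x$n_calibration))
  cat(sprintf("  wildtype freq    : %.1f%% (ceiling %.1f%%)\n",
              100 * x$wt_frequency_at_threshold, 100 * x$target_ceiling))
  if (length(x$excluded_missing_ctf) > 0) {
    cat(sprintf("  excluded (missing CTF): %d\n", length(x$excluded_missing_ctf)))
  }
  invisible(x)
}

#' Compare CTF between KRAS wildtype and mutant samples
#'
#' Two-sided Wilcoxon rank-sum comparison of per-sample CTF values
#' between the two KRAS groups, with group medians.
#'
#' @param metrics data.frame with columns \code{ctf} and \code{kras_status}.
#' @return list with \code{median_wildtype}, \code{median_mutant},
#'   \code{p.value}, \code{n_wildtype}, \code{n_mutant}.
#' @export
compare_ctf_by_kras <- function(metrics) {
  m <- metrics[!is.na(metrics$ctf), , drop = FALSE]
  wt <- m$ctf[m$kras_status == "wildtype"]
  mut <- m$ctf[m$kras_status == "mutant"]
  if (length(wt) == 0 || length(mut) == 0) {
    stop("both KRAS groups must be nonempty")
  }
  ws <- wilcoxon_ranksum(wt, mut)
  list(
    median_wildtype = stats::median(wt),
    median_mutant = stats::median(mut),
    p.value = ws$p.value,
    n_wildtype = length(wt),
    n_mutant = length(mut)
  )
}
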