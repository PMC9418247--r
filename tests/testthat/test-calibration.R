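test_that("threshold application retains ties and handles extremes", {
  ctf <- c(0.010, 0.020, 0.030)
  expect_equal(sum(apply_ctf_threshold(ctf, 0.0168)), 2)
  expect_true(all(apply_ctf_threshold(ctf, 0)))
  expect_equal(sum(apply_ctf_threshold(ctf, 0.05)), 0)
  expect_true(apply_ctf_threshold(0.0168, 0.0168))  # tie retained
})

test_that("calibration scans observed CTFs and stops at the prevalence ceiling", {
  m <- data.frame(
    sample_id = sprintf("S%02d", 1:16),
    ctf = c(1:4, 5:16) / 100,
    kras_status = rep(c("wildtype", "mutant"), c(4, 12))
  )
  cal <- calibrate_ctf_threshold(m, target_ceiling = 0.13, retention_floor = 0.5)
  expect_equal(cal$chosen_threshold, 0.04)
  expect_equal(cal$wt_frequency_at_threshold, 1 / 13)
  expect_equal(length(cal$retained_ids), 13)
  # hand-scan trajectory: 4/16 -> 3/15 -> 2/14 -> 1/13
  expect_equal(cal$trajectory$wt_frequency[1:4],
               c(4 / 16, 3 / 15, 2 / 14, 1 / 13))

  # ceiling already met at the minimum observed CTF: nothing filtered
  m2 <- data.frame(sample_id = 1:20, ctf = (1:20) / 100,
                   kras_status = rep(c("wildtype", "mutant"), c(2, 18)))
  cal2 <- calibrate_ctf_threshold(m2, 0.13, 0.5)
  expect_equal(cal2$chosen_threshold, min(m2$ctf))
  expect_equal(length(cal2$retained_ids), 20)

  all_wt <- data.frame(sample_id = 1:5, ctf = (1:5) / 100,
                       kras_status = "wildtype")
  expect_error(calibrate_ctf_threshold(all_wt, 0.13, 0.5), "degenerate")

  never <- data.frame(sample_id = 1:10, ctf = (1:10) / 100,
                      kras_status = rep(c("wildtype", "mutant"), 5))
  expect_error(calibrate_ctf_threshold(never, 0.05, 0.9), "no qualifying threshold")
})

test_that("trajectory matches a naive-loop recount and retention is monotone", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    m <- data.frame(
      sample_id = seq_len(n),
      ctf = round(runif(n, 0.001, 0.2), 3),  # rounding creates ties
      kras_status = sample(c("wildtype", "mutant"), n, replace = TRUE,
                           prob = c(0.3, 0.7))
    )
    cal <- try(calibrate_ctf_threshold(m, 0.25, 0.1), silent = TRUE)
    oracle <- calibration_naive_oracle(m$ctf, m$kras_status)
    if (inherits(cal, "try-error")) next
    expect_equal(cal$trajectory$threshold, oracle$threshold)
    expect_equal(cal$trajectory$n_retained, oracle$n_retained)
    expect_equal(cal$trajectory$wt_frequency, oracle$wt_frequency)
    expect_true(all(diff(cal$trajectory$n_retained) <= 0))
    expect_true(cal$wt_frequency_at_threshold <= 0.25)
    expect_true(length(cal$retained_ids) / cal$n_calibration >= 0.1)
  }
})

test_that("relaxing the ceiling never raises the chosen threshold", {
  set.seed(23)
  kras <- sample(c("wildtype", "mutant"), 80, TRUE, prob = c(0.3, 0.7))
  m <- data.frame(
    sample_id = 1:80,
    # wildtype samples shed less, so raising the threshold depletes them
    ctf = ifelse(kras == "wildtype", runif(80, 0.001, 0.05),
                 runif(80, 0.01, 0.15)),
    kras_status = kras
  )
  ceilings <- c(0.12, 0.15, 0.2, 0.25, 0.3)
  thr <- vapply(ceilings, function(cl) {
    out <- try(calibrate_ctf_threshold(m, cl, 0.05)$chosen_threshold,
               silent = TRUE)
    if (inherits(out, "try-error")) NA_real_ else out
  }, numeric(1))
  thr <- thr[!is.na(thr)]
  expect_gt(length(thr), 1)
  expect_true(all(diff(thr) <= 0))
})

test_that("samples with missing CTF are excluded from calibration and flagged", {
  m <- data.frame(
    sample_id = sprintf("S%02d", 1:17),
    ctf = c(NA, c(1:4, 5:16) / 100),
    kras_status = c("wildtype", rep(c("wildtype", "mutant"), c(4, 12)))
  )
  cal <- calibrate_ctf_threshold(m, 0.13, 0.5)
  expect_equal(cal$excluded_missing_ctf, "S01")
  expect_equal(cal$n_calibration, 16)
  expect_equal(cal$chosen_threshold, 0.04)
})

test_that("CTF comparison by KRAS group reports medians and the rank-sum p", {
  m <- data.frame(ctf = c(1, 2, 3, 10, 11, 12) / 100,
                  kras_status = rep(c("wildtype", "mutant"), each = 3))
  out <- compare_ctf_by_kras(m)
  expect_equal(out$p.value, 0.1)
  expect_equal(out$median_wildtype, 0.02)
  expect_equal(out$median_mutant, 0.11)
  same <- data.frame(ctf = rep(c(1, 2, 3) / 100, 2),
                     kras_status = rep(c("wildtype", "mutant"), each = 3))
  expect_equal(compare_ctf_by_kras(same)$p.value, 1)
  expect_error(compare_ctf_by_kras(data.frame(ctf = 0.1, kras_status = "mutant")),
               "nonempty")
})
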