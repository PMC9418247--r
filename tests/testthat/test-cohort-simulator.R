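test_that("allocation arithmetic and stratified blocks behave as designed", {
  co <- simulate_cohort(simulation_config(n_patients = 180, seed = 1))
  expect_equal(sum(co$clinical$arm == "chemo_ici"), 120)
  expect_equal(sum(co$clinical$arm == "chemo"), 60)

  expect_equal(as.integer(table(assign_arms(9, c(2, 1), seed = 4))), c(6L, 3L))
  a10 <- as.integer(table(assign_arms(10, c(2, 1), seed = 4)))
  expect_true(all(a10 == c(7, 3)) || all(a10 == c(6, 4)))
  strata <- rep(c("s1", "s2"), each = 6)
  a2 <- assign_arms(12, c(2, 1), strata = strata, seed = 4)
  for (s in c("s1", "s2")) {
    expect_equal(as.integer(table(a2[strata == s])), c(4L, 2L))
  }
})

test_that("identical config and seed reproduce the cohort byte-for-byte", {
  cfg <- simulation_config(n_patients = 3, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$variants, b$variants)
  expect_identical(a$truth, b$truth)
})

test_that("degenerate KRAS prevalence of 1 makes every truth record mutant", {
  cfg <- simulation_config(
    n_patients = 50, seed = 2,
    gene_prevalence = c(KRAS = 1.0, TP53 = 0.65, CDKN2A = 0.22, SMAD4 = 0.13)
  )
  co <- simulate_cohort(cfg)
  expect_true(all(co$truth$kras_truth == "mutant"))
})

test_that("invalid configuration values are rejected with the field named", {
  expect_error(simulation_config(seed = 1, ecog1_prob = 1.5), "ecog1_prob")
  expect_error(simulation_config(seed = 1, hr_arm = -1), "hr_arm")
  expect_error(simulation_config(seed = 1, allocation_ratio = c(0, 1)),
               "allocation_ratio")
  expect_error(simulation_config(seed = 1, gene_prevalence = c(TP53 = 0.5)),
               "KRAS")
  expect_error(simulation_config(n_patients = 10), "seed")
})

test_that("variant generation respects the KRAS truth and call-count constraints", {
  cfg <- simulation_config(n_patients = 60, seed = 9)
  co <- simulate_cohort(cfg)
  v <- co$variants
  expect_true(all(v$sample_id %in% co$truth$patient_id))
  for (i in seq_len(nrow(co$truth))) {
    vi <- v[v$sample_id == co$truth$patient_id[i], ]
    kras_som <- vi$gene == "KRAS" & vi$origin == "somatic" &
      vi$effect %in% c("missense", "nonsense", "frameshift", "inframe_indel")
    if (co$truth$kras_truth[i] == "mutant") {
      expect_true(any(kras_som))
    } else {
      expect_false(any(vi$gene == "KRAS" & vi$origin == "somatic"))
    }
    lof <- filter_lof(vi)
    expect_gte(sum(lof$origin == "somatic"), 1)
    expect_gte(sum(lof$origin == "germline"), 1)
  }
  expect_true(all(v$allele_fraction > 0 & v$allele_fraction <= 1))
  germ <- v$allele_fraction[v$origin == "germline"]
  expect_true(all((germ >= 0.45 & germ <= 0.55) | germ >= 0.97))
})

test_that("the clonal variant makes the max-MAF estimator exact on clean config", {
  cfg <- simulation_config(n_patients = 40, seed = 12,
                           chip_variant_prob = 0, cna_flag_prob = 0)
  co <- simulate_cohort(cfg)
  for (i in seq_len(nrow(co$truth))) {
    vi <- co$variants[co$variants$sample_id == co$truth$patient_id[i], ]
    expect_equal(estimate_sample_ctf(vi), co$truth$true_ctf[i],
                 tolerance = 1e-9)
  }
  # max somatic MAF equals the clonal MAF: factor-1 variant dominates
  one <- data.frame(patient_id = "P1", true_ctf = 0.5,
                    kras_truth = "mutant", msi_truth = FALSE)
  set.seed(1)
  vv <- simulate_variants(one, cfg)
  expect_equal(max(vv$allele_fraction[vv$origin == "somatic"]),
               ctf_to_maf(0.5), tolerance = 1e-12)
})

test_that("KRAS calls from variants agree perfectly with the generating truth", {
  cfg <- simulation_config(n_patients = 120, seed = 31)
  co <- simulate_cohort(cfg)
  m <- compute_sample_metrics(co$variants, cfg$panel,
                              sample_ids = co$truth$patient_id)
  expect_equal(m$kras_status[match(co$truth$patient_id, m$sample_id)],
               co$truth$kras_truth)
})

test_that("generated gene frequencies recover the configured prevalences", {
  cfg <- simulation_config(n_patients = 5000, seed = 19)
  co <- simulate_cohort(cfg)
  land <- summarize_landscape(
    co$variants,
    metrics = compute_sample_metrics(co$variants, cfg$panel,
                                     sample_ids = co$truth$patient_id)
  )
  for (g in names(cfg$gene_prevalence)) {
    p <- cfg$gene_prevalence[[g]]
    obs <- land$gene_frequency$frequency[land$gene_frequency$gene == g]
    se <- sqrt(p * (1 - p) / 5000)
    expect_lt(abs(obs - p), 3 * se)
  }
  # wildtype patients shed less: rank-sum detects the direction at large n
  m <- compute_sample_metrics(co$variants, cfg$panel,
                              sample_ids = co$truth$patient_id)
  cmp <- compare_ctf_by_kras(m)
  expect_lt(cmp$median_wildtype, cmp$median_mutant)
  expect_lt(cmp$p.value, 1e-6)
})

test_that("PFS never exceeds OS and the zero horizon censors everyone at 0", {
  co <- simulate_cohort(simulation_config(n_patients = 100, seed = 3))
  expect_true(all(co$clinical$pfs_months <= co$clinical$os_months + 1e-12))
  expect_true(all(co$clinical$os_months >= 0))

  cfg0 <- simulation_config(n_patients = 20, seed = 3, horizon_months = 0)
  co0 <- simulate_cohort(cfg0)
  expect_true(all(co0$clinical$os_months == 0))
  expect_true(all(!co0$clinical$os_event))
})
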