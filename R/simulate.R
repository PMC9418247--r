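# Synthetic liquid-biopsy cohort generator for a two-arm metastatic-PDAC
# trial: clinical covariates under stratified 2:1 block randomization,
# latent circulating tumor fraction (stochastically lower in
# KRAS-wildtype patients), per-patient variant calls from a targeted
# panel, and proportional-hazards survival tied to arm and KRAS status.

#' Gene-to-chromosome lookup bundled with the package
#'
#' Small panel-gene table (gene symbol, chromosome, representative
#' 1-based base position) used to place synthetic variant calls. KRAS is
#' on chromosome 12 and therefore eligible for CTF estimation; KDM6A (on
#' X) exercises the autosome rule.
#'
#' @return data.frame with columns \code{gene}, \code{chrom}, \code{base_pos}.
#' @export
gene_chromosomes <- function() {
  utils::read.csv(
    system.file("extdata", "gene_chromosomes.csv", package = "ctdnatrial"),
    stringsAsFactors = FALSE, colClasses = c("character", "character", "integer")
  )
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || any(x < 0 | x > 1)) {
    stop(name, " must be a probability in [0, 1]")
  }
}
.check_pos <- function(x, name) {
  if (!is.numeric(x) || any(x <= 0)) stop(name, " must be positive")
}

#' Simulation configuration for a synthetic trial cohort
#'
#' Defaults emulate a 180-patient metastatic pancreatic
#' adenocarcinoma cohort: 2:1 allocation stratified by ECOG (77% ECOG 1)
#' and prior adjuvant therapy (11%), driver-gene somatic prevalences
#' (KRAS 77%, TP53 65%, CDKN2A 22%, SMAD4 13%), a single microsatellite-
#' instable patient in ~173 on average, control-arm median overall
#' survival 8.5 months, and a strong protective KRAS-wildtype hazard
#' ratio of 0.40. The latent circulating tumor fraction is log-normal
#' within KRAS group with a lower location for wildtype patients,
#' reflecting lower tumor shedding in that subgroup.
#'
#' @param n_patients cohort size.
#' @param allocation_ratio integer pair, experimental:control.
#' @param seed integer RNG seed (mandatory).
#' @param ecog1_prob probability of ECOG performance status 1 (vs 0).
#' @param prior_adjuvant_prob probability of prior adjuvant chemotherapy.
#' @param gene_prevalence named vector of per-gene somatic driver
#'   mutation probabilities; must include KRAS.
#' @param msi_prob probability of microsatellite instability.
#' @param ctf_meanlog,ctf_sdlog named (wildtype, mutant) log-normal
#'   location and scale for the latent CTF; draws above 0.95 are
#'   resampled so CTF stays inside (0, 1).
#' @param somatic_lof_rate,germline_lof_rate Poisson rates; per-patient
#'   loss-of-function counts are 1 + Poisson(rate), giving a median of 5
#'   at the default 4.2 while guaranteeing at least one call of each
#'   origin.
#' @param somatic_synonymous_rate Poisson rate for somatic synonymous
#'   SNVs (count toward bTMB but not the LoF landscape).
#' @param chip_variant_prob probability of one incidental CHIP-gene
#'   somatic call (low allele fraction, CTF-independent).
#' @param msi_btmb reference bTMB (mut/Mb) for microsatellite-instable
#'   patients; their somatic SNV count is inflated to match.
#' @param control_median_os_months control-arm median overall survival.
#' @param hr_arm hazard ratio, experimental vs control arm (1 = null).
#' @param hr_kras_wt hazard ratio, KRAS wildtype vs mutant.
#' @param pfs_beta Beta(a, b) parameters for the PFS/OS fraction.
#' @param accrual_months,horizon_months uniform accrual window and
#'   administrative censoring horizon (both from study start).
#' @param response_probs per-arm multinomial over CR/PR/SD/PD/NE;
#'   defaults reproduce objective response rates of ~30% vs ~23% and
#'   disease control rates of ~70% vs ~57%.
#' @param qol_change_mean per-arm mean change from baseline (points).
#' @param qol_change_sd standard deviation of QoL change scores.
#' @param lymphocyte_ge3_prob per-arm probability of grade >=3
#'   lymphocyte elevation.
#' @param clonal_factor_range subclonal allele-fraction multiplier range
#'   for non-clonal variants; the designated clonal variant has factor
#'   exactly 1 so the maximum-MAF CTF estimator is identifiable.
#' @param cna_flag_prob probability a non-clonal somatic call sits in a
#'   gene with a detectable copy-number change.
#' @param panel a [panel_spec()].
#' @return object of class \code{simulation_config}.
#' @export
simulation_config <- function(
    n_patients = 180,
    allocation_ratio = c(2, 1),
    seed,
    ecog1_prob = 0.77,
    prior_adjuvant_prob = 0.11,
    gene_prevalence = c(KRAS = 0.77, TP53 = 0.65, CDKN2A = 0.22, SMAD4 = 0.13),
    msi_prob = 1 / 173,
    ctf_meanlog = c(wildtype = log(0.012), mutant = log(0.045)),
    ctf_sdlog = c(wildtype = 1.0, mutant = 1.0),
    somatic_lof_rate = 4.2,
    germline_lof_rate = 4.2,
    somatic_synonymous_rate = 5.0,
    chip_variant_prob = 0.10,
    msi_btmb = 52.9,
    control_median_os_months = 8.5,
    hr_arm = 1.0,
    hr_kras_wt = 0.40,
    pfs_beta = c(5, 4),
    accrual_months = 23,
    horizon_months = 40,
    response_probs = list(
      chemo_ici = c(CR = 0.02, PR = 0.28, SD = 0.40, PD = 0.25, NE = 0.05),
      chemo = c(CR = 0.01, PR = 0.22, SD = 0.34, PD = 0.38, NE = 0.05)
    ),
    qol_change_mean = c(chemo_ici = -5, chemo = -5),
    qol_change_sd = 15,
    lymphocyte_ge3_prob = c(chemo_ici = 0.38, chemo = 0.20),
    clonal_factor_range = c(0.3, 1.0),
    cna_flag_prob = 0.05,
    panel = panel_spec()) {
  if (missing(seed) || !is.numeric(seed)) stop("seed is mandatory (integer)")
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop("n_patients must be a positive integer")
  }
  if (length(allocation_ratio) != 2 || any(allocation_ratio < 1) ||
      any(allocation_ratio != round(allocation_ratio))) {
    stop("allocation_ratio must be two integers >= 1")
  }
  .check_prob(ecog1_prob, "ecog1_prob")
  .check_prob(prior_adjuvant_prob, "prior_adjuvant_prob")
  .check_prob(gene_prevalence, "gene_prevalence")
  if (!"KRAS" %in% names(gene_prevalence)) {
    stop("gene_prevalence must include KRAS")
  }
  .check_prob(msi_prob, "msi_prob")
  .check_prob(chip_variant_prob, "chip_variant_prob")
  .check_prob(cna_flag_prob, "cna_flag_prob")
  .check_prob(lymphocyte_ge3_prob, "lymphocyte_ge3_prob")
  if (!all(c("wildtype", "mutant") %in% names(ctf_meanlog)) ||
      !all(c("wildtype", "mutant") %in% names(ctf_sdlog))) {
    stop("ctf_meanlog and ctf_sdlog need 'wildtype' and 'mutant' entries")
  }
  .check_pos(ctf_sdlog, "ctf_sdlog")
  .check_pos(control_median_os_months, "control_median_os_months")
  .check_pos(hr_arm, "hr_arm")
  .check_pos(hr_kras_wt, "hr_kras_wt")
  .check_pos(pfs_beta, "pfs_beta")
  .check_pos(qol_change_sd, "qol_change_sd")
  if (accrual_months < 0 || horizon_months < 0) {
    stop("accrual_months and horizon_months must be nonnegative")
  }
  for (p in response_probs) {
    .check_prob(p, "response_probs")
    if (abs(sum(p) - 1) > 1e-8) stop("response_probs must sum to 1 per arm")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      allocation_ratio = as.integer(allocation_ratio),
      seed = as.integer(seed),
      ecog1_prob = ecog1_prob,
      prior_adjuvant_prob = prior_adjuvant_prob,
      gene_prevalence = gene_prevalence,
      msi_prob = msi_prob,
      ctf_meanlog = ctf_meanlog,
      ctf_sdlog = ctf_sdlog,
      somatic_lof_rate = somatic_lof_rate,
      germline_lof_rate = germline_lof_rate,
      somatic_synonymous_rate = somatic_synonymous_rate,
      chip_variant_prob = chip_variant_prob,
      msi_btmb = msi_btmb,
      control_median_os_months = control_median_os_months,
      hr_arm = hr_arm,
      hr_kras_wt = hr_kras_wt,
      pfs_beta = pfs_beta,
      accrual_months = accrual_months,
      horizon_months = horizon_months,
      response_probs = response_probs,
      qol_change_mean = qol_change_mean,
      qol_change_sd = qol_change_sd,
      lymphocyte_ge3_prob = lymphocyte_ge3_prob,
      clonal_factor_range = clonal_factor_range,
      cna_flag_prob = cna_flag_prob,
      panel = panel
    ),
    class = "simulation_config"
  )
}

#' Stratified permuted-block arm assignment
#'
#' Within each stratum, complete blocks of size \code{sum(ratio)} carry
#' the exact allocation ratio in random order; partial final blocks are
#' filled from a pooled remainder constrained so the cohort-level totals
#' match the target allocation exactly (up to rounding of
#' \code{n * ratio / sum(ratio)}).
#'
#' @param n number of patients.
#' @param ratio integer pair, experimental:control.
#' @param strata optional stratum label per patient.
#' @param labels arm labels, experimental first.
#' @param seed optional RNG seed.
#' @return factor of arm labels, experimental level first.
#' @export
assign_arms <- function(n, ratio = c(2, 1), strata = NULL,
                        labels = c("chemo_ici", "chemo"), seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(strata)) strata <- rep("all", n)
  strata <- factor(strata)
  k <- sum(ratio)
  target_exp <- round(n * ratio[1] / k)
  arm <- character(n)
  rem_idx <- integer(0)
  n_exp_full <- 0L
  for (s in levels(strata)) {
    idx <- which(strata == s)
    m <- length(idx)
    n_blocks <- m %/% k
    block_assign <- unlist(lapply(seq_len(n_blocks), function(b) {
      sample(rep(labels, ratio))
    }))
    take <- n_blocks * k
    if (take > 0) {
      arm[idx[seq_len(take)]] <- block_assign
      n_exp_full <- n_exp_full + n_blocks * ratio[1]
    }
    if (m > take) rem_idx <- c(rem_idx, idx[(take + 1):m])
  }
  if (length(rem_idx) > 0) {
    need_exp <- min(max(target_exp - n_exp_full, 0L), length(rem_idx))
    pool <- sample(rep(labels, c(need_exp, length(rem_idx) - need_exp)))
    arm[rem_idx] <- pool
  }
  factor(arm, levels = labels)
}

# Truncated log-normal draw kept inside (0, cap) by resampling the tail.
.rlnorm_trunc <- function(n, meanlog, sdlog, cap = 0.95) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  bad <- which(x >= cap)
  while (length(bad) > 0) {
    x[bad] <- stats::rlnorm(length(bad), meanlog, sdlog)
    bad <- bad[x[bad] >= cap]
  }
  x
}

.random_snv <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  list(ref = ref, alt = unname(alt))
}

#' Simulate the variant calls of one patient
#'
#' Generates somatic loss-of-function calls (driver genes by prevalence,
#' passengers filling up a count with median 5), somatic synonymous SNVs,
#' germline loss-of-function calls (allele fractions near 0.5 or 1.0),
#' and optionally one low-allele-fraction CHIP-gene call. Somatic allele
#' fractions are \code{ctf_to_maf(true_ctf)} times a per-variant clonal
#' factor; one designated autosomal, non-CNA variant (the KRAS driver
#' when present) has factor exactly 1, so the maximum-MAF CTF estimator
#' can recover the latent truth. A KRAS-mutant truth always yields at
#' least one somatic nonsynonymous KRAS call; a wildtype truth never
#' yields any.
#'
#' @param truth one-row data.frame with \code{patient_id},
#'   \code{true_ctf}, \code{kras_truth}, \code{msi_truth}.
#' @param config a [simulation_config()].
#' @return variant-call data.frame (see [validate_variants()]).
#' @export
simulate_variants <- function(truth, config) {
  genes <- gene_chromosomes()
  chip <- config$panel$chip_genes
  germline_pool <- c("ATM", "BRCA1", "BRCA2", "PALB2", "CHEK2",
                     "MLH1", "MSH2", "MSH6")
  driver_genes <- names(config$gene_prevalence)
  passenger_pool <- setdiff(genes$gene, c(driver_genes, chip))

  id <- truth$patient_id
  maf_clonal <- ctf_to_maf(truth$true_ctf)
  cf <- config$clonal_factor_range

  # drivers present in this patient; KRAS fixed by the latent truth
  mutated <- driver_genes[stats::runif(length(driver_genes)) <
                            config$gene_prevalence]
  mutated <- setdiff(mutated, "KRAS")
  if (truth$kras_truth == "mutant") mutated <- c("KRAS", mutated)

  n_som <- max(1 + stats::rpois(1, config$somatic_lof_rate),
               length(mutated), 1)
  n_passenger <- n_som - length(mutated)
  som_genes <- c(mutated,
                 sample(passenger_pool, n_passenger, replace = TRUE))
  som_eff <- sample(c("missense", "nonsense", "frameshift", "inframe_indel"),
                    n_som, replace = TRUE, prob = c(0.60, 0.15, 0.15, 0.10))
  # KRAS drivers are activating hotspot missense changes
  som_eff[som_genes == "KRAS"] <- "missense"

  factors <- stats::runif(n_som, cf[1], cf[2])
  cna <- stats::runif(n_som) < config$cna_flag_prob
  gene_chrom <- genes$chrom[match(som_genes, genes$gene)]
  # designated clonal variant: KRAS when mutant, else the first autosomal call
  clonal_idx <- if (truth$kras_truth == "mutant") {
    which(som_genes == "KRAS")[1]
  } else {
    cand <- which(gene_chrom %in% as.character(1:22))
    if (length(cand) == 0) {
      som_genes[1] <- sample(setdiff(passenger_pool, "KDM6A"), 1)
      gene_chrom[1] <- genes$chrom[match(som_genes[1], genes$gene)]
      1L
    } else cand[1]
  }
  factors[clonal_idx] <- 1
  cna[clonal_idx] <- FALSE

  som <- data.frame(
    sample_id = id,
    gene = som_genes,
    effect = som_eff,
    allele_fraction = pmin(maf_clonal * factors, 1),
    origin = "somatic",
    cna_flag = cna,
    stringsAsFactors = FALSE
  )

  # somatic synonymous SNVs (bTMB only); inflated count under MSI
  n_syn <- stats::rpois(1, config$somatic_synonymous_rate)
  if (truth$msi_truth) {
    n_syn <- n_syn + stats::rpois(
      1, config$msi_btmb * config$panel$effective_coding_size_mb
    )
  }
  if (n_syn > 0) {
    syn <- data.frame(
      sample_id = id,
      gene = sample(passenger_pool, n_syn, replace = TRUE),
      effect = "synonymous",
      allele_fraction = pmin(maf_clonal * stats::runif(n_syn, cf[1], cf[2]), 1),
      origin = "somatic",
      cna_flag = stats::runif(n_syn) < config$cna_flag_prob,
      stringsAsFactors = FALSE
    )
    som <- rbind(som, syn)
  }

  # incidental CHIP-gene call: hematopoietic clone, CTF-independent AF
  if (stats::runif(1) < config$chip_variant_prob) {
    som <- rbind(som, data.frame(
      sample_id = id,
      gene = sample(chip, 1),
      effect = sample(c("missense", "nonsense"), 1),
      allele_fraction = stats::runif(1, 0.002, 0.02),
      origin = "somatic",
      cna_flag = FALSE,
      stringsAsFactors = FALSE
    ))
  }

  # germline loss-of-function calls: heterozygous or (rarely) homozygous
  n_germ <- 1 + stats::rpois(1, config$germline_lof_rate)
  hom <- stats::runif(n_germ) < 0.1
  germ <- data.frame(
    sample_id = id,
    gene = sample(germline_pool, n_germ, replace = TRUE),
    effect = sample(c("missense", "nonsense", "frameshift", "inframe_indel"),
                    n_germ, replace = TRUE, prob = c(0.5, 0.2, 0.2, 0.1)),
    allele_fraction = ifelse(hom, stats::runif(n_germ, 0.97, 1.0),
                             stats::runif(n_germ, 0.45, 0.55)),
    origin = "germline",
    cna_flag = FALSE,
    stringsAsFactors = FALSE
  )

  v <- rbind(som, germ)
  v$chrom <- genes$chrom[match(v$gene, genes$gene)]
  v$is_snv <- v$effect %in% c("missense", "nonsense", "synonymous")
  v$is_coding <- TRUE
  base <- genes$base_pos[match(v$gene, genes$gene)]
  v$pos <- base + sample.int(50000L, nrow(v), replace = TRUE)
  snv <- .random_snv(nrow(v))
  v$ref <- snv$ref
  v$alt <- snv$alt
  indel <- !v$is_snv
  v$ref[indel] <- paste0(v$ref[indel], "A")
  v[, .variant_columns]
}

#' Simulate survival endpoints under exponential proportional hazards
#'
#' Overall survival is exponential with hazard
#' \code{log(2)/control_median * hr_arm^[experimental] * hr_kras_wt^[wildtype]};
#' PFS is OS times a Beta-distributed fraction. Entry times are uniform
#' over the accrual window and both endpoints are administratively
#' censored at the study horizon.
#'
#' @param arm factor/character, \code{"chemo_ici"} or \code{"chemo"}.
#' @param kras_truth character, \code{"mutant"} or \code{"wildtype"}.
#' @param config a [simulation_config()].
#' @param seed optional RNG seed.
#' @return data.frame with \code{os_months}, \code{os_event},
#'   \code{pfs_months}, \code{pfs_event}, \code{entry_months}.
#' @export
simulate_survival <- function(arm, kras_truth, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(arm)
  rate <- log(2) / config$control_median_os_months *
    ifelse(arm == "chemo_ici", config$hr_arm, 1) *
    ifelse(kras_truth == "wildtype", config$hr_kras_wt, 1)
  os_raw <- stats::rexp(n, rate)
  pfs_raw <- os_raw * stats::rbeta(n, config$pfs_beta[1], config$pfs_beta[2])
  entry <- stats::runif(n, 0, config$accrual_months)
  fu <- pmax(config$horizon_months - entry, 0)
  data.frame(
    os_months = pmin(os_raw, fu),
    os_event = os_raw <= fu,
    pfs_months = pmin(pfs_raw, fu),
    pfs_event = pfs_raw <= fu,
    entry_months = entry
  )
}

#' Simulate a complete synthetic trial cohort
#'
#' Draws clinical covariates, randomizes arms by stratified permuted
#' blocks (ECOG x prior adjuvant strata), assigns latent KRAS status and
#' circulating tumor fraction, generates per-patient variant calls,
#' survival endpoints, RECIST best response, QoL change scores and one
#' safety flag. Identical configurations (including seed) reproduce
#' identical output.
#'
#' @param config a [simulation_config()].
#' @return object of class \code{ctdna_cohort}: list with
#'   \code{clinical} (one row per patient), \code{variants} (variant-call
#'   table), \code{truth} (latent per-patient truth), \code{config}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("PT%04d", seq_len(n))

  ecog <- stats::rbinom(n, 1, config$ecog1_prob)
  prior <- stats::runif(n) < config$prior_adjuvant_prob
  stratum <- interaction(ecog, prior, drop = FALSE)
  arm <- assign_arms(n, config$allocation_ratio, strata = stratum)

  kras <- ifelse(stats::runif(n) < config$gene_prevalence["KRAS"],
                 "mutant", "wildtype")
  msi <- stats::runif(n) < config$msi_prob
  true_ctf <- numeric(n)
  for (grp in c("wildtype", "mutant")) {
    sel <- kras == grp
    true_ctf[sel] <- .rlnorm_trunc(sum(sel), config$ctf_meanlog[grp],
                                   config$ctf_sdlog[grp])
  }
  truth <- data.frame(patient_id = ids, true_ctf = true_ctf,
                      kras_truth = kras, msi_truth = msi,
                      stringsAsFactors = FALSE)

  variants <- do.call(rbind, lapply(seq_len(n), function(i) {
    simulate_variants(truth[i, , drop = FALSE], config)
  }))
  rownames(variants) <- NULL

  surv <- simulate_survival(arm, kras, config)

  best_response <- character(n)
  qol_mean <- numeric(n)
  lymph_p <- numeric(n)
  for (a in levels(arm)) {
    sel <- arm == a
    p <- config$response_probs[[a]]
    best_response[sel] <- sample(names(p), sum(sel), replace = TRUE, prob = p)
    qol_mean[sel] <- config$qol_change_mean[[a]]
    lymph_p[sel] <- config$lymphocyte_ge3_prob[[a]]
  }

  clinical <- data.frame(
    patient_id = ids,
    arm = as.character(arm),
    ecog = ecog,
    prior_adjuvant = prior,
    os_months = surv$os_months,
    os_event = surv$os_event,
    pfs_months = surv$pfs_months,
    pfs_event = surv$pfs_event,
    best_response = best_response,
    qol_change_w8 = stats::rnorm(n, qol_mean, config$qol_change_sd),
    qol_change_w16 = stats::rnorm(n, qol_mean, config$qol_change_sd),
    grade_ge3_lymphocyte_elevation = stats::runif(n) < lymph_p,
    stringsAsFactors = FALSE
  )

  structure(
    list(clinical = clinical, variants = variants, truth = truth,
         config = config),
    class = "ctdna_cohort"
  )
}

#' @export
print.ctdna_cohort <- function(x, ...) {
  tab <- table(x$clinical$arm)
  cat(sprintf("Synthetic ctDNA trial cohort: %d patients (%s), %d variant calls\n",
              nrow(x$clinical),
              paste(sprintf("%s = %d", names(tab), tab), collapse = ", "),
              nrow(x$variants)))
  cat(sprintf("  KRAS mutant (truth): %d (%.0f%%); seed %d\n",
              sum(x$truth$kras_truth == "mutant"),
              100 * mean(x$truth$kras_truth == "mutant"),
              x$config$seed))
  invisible(x)
}
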