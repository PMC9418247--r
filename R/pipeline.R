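# Pipeline orchestration: simulate -> metrics -> calibrate -> analyze ->
# report, as independently runnable stages with one configured seed,
# per-stage derived RNG streams, structured logs and a digest manifest.

# Derived per-stage seed: deterministic, stage-specific, < 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.numeric(seed) * 7919 + h) %% 2147483647
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Read a pipeline configuration file
#'
#' YAML key/value configuration; every [simulation_config()] field can be
#' overridden, plus \code{calibration} (\code{target_ceiling},
#' \code{retention_floor}) and \code{panel} settings. The seed is
#' mandatory for pipeline runs.
#'
#' @param path YAML file.
#' @return list with \code{sim} (a \code{simulation_config}) and
#'   \code{calibration} settings.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stop("config error: 'seed' is mandatory")
  panel_args <- raw$panel
  panel <- if (is.null(panel_args)) panel_spec() else
    do.call(panel_spec, panel_args)
  calib <- list(
    target_ceiling = raw$calibration$target_ceiling %||% 0.13,
    retention_floor = raw$calibration$retention_floor %||% 0.5
  )
  sim_args <- raw[setdiff(names(raw), c("calibration", "panel"))]
  for (nm in c("gene_prevalence", "ctf_meanlog", "ctf_sdlog",
               "qol_change_mean", "lymphocyte_ge3_prob")) {
    if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
  }
  for (nm in c("allocation_ratio", "pfs_beta", "clonal_factor_range")) {
    if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- as.numeric(unlist(sim_args[[nm]]))
  }
  if (!is.null(sim_args$response_probs)) {
    sim_args$response_probs <- lapply(sim_args$response_probs, unlist)
  }
  sim_args$panel <- panel
  sim <- do.call(simulation_config, sim_args)
  list(sim = sim, calibration = calib)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulation stage: write the synthetic cohort to disk
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, named paths (clinical, truth, variants).
#' @export
stage_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config)
  paths <- c(
    clinical = file.path(out_dir, "clinical.csv"),
    truth = file.path(out_dir, "truth.csv"),
    variants = file.path(out_dir, "variants.vcf")
  )
  utils::write.csv(cohort$clinical, paths["clinical"], row.names = FALSE)
  utils::write.csv(cohort$truth, paths["truth"], row.names = FALSE)
  write_variants_vcf(cohort$variants, paths["variants"])
  .log_stage("simulate", "n = %d patients, %d variant calls, seed = %d",
             nrow(cohort$clinical), nrow(cohort$variants), config$seed)
  invisible(paths)
}

#' Metrics stage: per-sample ctDNA metrics from a VCF
#'
#' @param vcf_path cohort VCF.
#' @param out_dir output directory.
#' @param panel a [panel_spec()].
#' @param truth_path optional truth table supplying MSI status and the
#'   full sample roster.
#' @return invisibly, the metrics CSV path.
#' @export
stage_metrics <- function(vcf_path, out_dir, panel = panel_spec(),
                          truth_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  variants <- read_variants_vcf(vcf_path)
  msi <- NULL
  roster <- NULL
  if (!is.null(truth_path)) {
    truth <- utils::read.csv(truth_path, stringsAsFactors = FALSE)
    msi <- stats::setNames(ifelse(truth$msi_truth, "MSI", "MSS"),
                           truth$patient_id)
    roster <- truth$patient_id
  }
  metrics <- compute_sample_metrics(variants, panel, msi_status = msi,
                                    sample_ids = roster)
  path <- file.path(out_dir, "metrics.csv")
  utils::write.csv(metrics, path, row.names = FALSE)
  land <- summarize_landscape(variants, metrics)
  utils::write.csv(land$gene_frequency,
                   file.path(out_dir, "gene_frequency.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(btmb_summary = as.list(land$btmb_summary),
         n_samples = nrow(metrics)),
    file.path(out_dir, "landscape.json"), auto_unbox = TRUE, digits = NA
  )
  .log_stage("metrics", "%d samples; bTMB median %.2f mut/Mb; KRAS wildtype %.1f%%",
             nrow(metrics), stats::median(metrics$btmb),
             100 * mean(metrics$kras_status == "wildtype"))
  invisible(path)
}

#' Calibration stage: prevalence-targeted CTF threshold
#'
#' @param metrics_path metrics CSV from [stage_metrics()].
#' @param out_dir output directory.
#' @param target_ceiling,retention_floor see [calibrate_ctf_threshold()].
#' @return invisibly, the calibration JSON path.
#' @export
stage_calibrate <- function(metrics_path, out_dir, target_ceiling = 0.13,
                            retention_floor = 0.5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- utils::read.csv(metrics_path, stringsAsFactors = FALSE)
  cal <- calibrate_ctf_threshold(metrics, target_ceiling, retention_floor)
  utils::write.csv(cal$trajectory, file.path(out_dir, "ctf_trajectory.csv"),
                   row.names = FALSE)
  path <- file.path(out_dir, "calibration.json")
  jsonlite::write_json(
    list(chosen_threshold = cal$chosen_threshold,
         wt_frequency_at_threshold = cal$wt_frequency_at_threshold,
         n_retained = length(cal$retained_ids),
         n_calibration = cal$n_calibration,
         target_ceiling = cal$target_ceiling,
         retention_floor = cal$retention_floor,
         retained_ids = cal$retained_ids,
         excluded_missing_ctf = cal$excluded_missing_ctf),
    path, auto_unbox = TRUE, digits = NA
  )
  .log_stage("calibrate", "chosen CTF threshold = %.4g (wildtype %.1f%%, retained %d/%d)",
             cal$chosen_threshold, 100 * cal$wt_frequency_at_threshold,
             length(cal$retained_ids), cal$n_calibration)
  invisible(path)
}

.comparison_record <- function(cmp) {
  list(
    comparison = cmp$comparison,
    median_by_group = as.list(cmp$median_by_group),
    hr = cmp$hr,
    ci90 = as.list(cmp$ci),
    logrank_p = cmp$logrank_p,
    n_by_group = as.list(as.integer(cmp$n_by_group)),
    events_by_group = as.list(as.integer(cmp$events_by_group))
  )
}

.surv_compare <- function(clin, endpoint, group, stratum) {
  time_col <- paste0(endpoint, "_months")
  event_col <- paste0(endpoint, "_event")
  stratified_cox(clin[[time_col]], clin[[event_col]], group, stratum)
}

# Subgroup comparisons (e.g. KRAS within one arm at small n) can have a
# monotone partial likelihood; record the failure explicitly instead of
# aborting the whole analysis stage.
.safe_comparison <- function(expr) {
  tryCatch(.comparison_record(expr), error = function(e) {
    list(error = conditionMessage(e))
  })
}

#' Analysis stage: trial statistics on the simulated cohort
#'
#' Runs the arm comparison (OS/PFS stratified Cox + log-rank, ORR/DCR
#' with CMH, QoL deterioration and safety Fisher tests), the
#' KRAS-stratified survival analyses (per arm and combined), the CTF
#' wildtype-vs-mutant comparison, and optionally the CTF-filtered
#' sensitivity analysis.
#'
#' @param clinical_path,metrics_path stage input CSVs.
#' @param out_dir output directory.
#' @param endpoints endpoints to analyze (\code{"os"}, \code{"pfs"}).
#' @param ctf_threshold optional CTF threshold for the filtered
#'   sensitivity analysis (e.g. from [stage_calibrate()]).
#' @return invisibly, the analyses JSON path.
#' @export
stage_analyze <- function(clinical_path, metrics_path, out_dir,
                          endpoints = c("os", "pfs"), ctf_threshold = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  clin <- utils::read.csv(clinical_path, stringsAsFactors = FALSE)
  metrics <- utils::read.csv(metrics_path, stringsAsFactors = FALSE)
  req <- c("patient_id", "arm", "ecog", "prior_adjuvant",
           "os_months", "os_event", "best_response")
  miss <- setdiff(req, names(clin))
  if (length(miss) > 0) {
    stop("clinical table is missing column(s): ", paste(miss, collapse = ", "))
  }
  clin$arm <- factor(clin$arm, levels = c("chemo", "chemo_ici"))
  stratum <- interaction(clin$ecog, clin$prior_adjuvant)
  m <- metrics[match(clin$patient_id, metrics$sample_id), , drop = FALSE]

  out <- list(n = nrow(clin))
  for (ep in endpoints) {
    out[[paste0(ep, "_by_arm")]] <-
      .comparison_record(.surv_compare(clin, ep, clin$arm, stratum))
  }

  # response rates + CMH on responder (CR/PR) vs not, stratified
  rr <- lapply(split(clin$best_response, clin$arm), orr_dcr)
  resp <- clin$best_response %in% c("CR", "PR")
  strata_tabs <- lapply(split(seq_len(nrow(clin)), stratum), function(ix) {
    matrix(c(sum(resp[ix] & clin$arm[ix] == "chemo_ici"),
             sum(!resp[ix] & clin$arm[ix] == "chemo_ici"),
             sum(resp[ix] & clin$arm[ix] == "chemo"),
             sum(!resp[ix] & clin$arm[ix] == "chemo")),
           nrow = 2, byrow = TRUE)
  })
  strata_tabs <- strata_tabs[vapply(strata_tabs, sum, numeric(1)) > 1]
  cmh <- cmh_response_test(array(unlist(strata_tabs),
                                 dim = c(2, 2, length(strata_tabs))))
  out$response <- list(
    orr = lapply(rr, function(r) r$orr),
    dcr = lapply(rr, function(r) r$dcr),
    cmh_or = cmh$or, cmh_ci90 = as.list(cmh$ci), cmh_p = cmh$p.value
  )

  # safety and QoL deterioration: Fisher exact by arm
  ae_tab <- table(clin$arm, factor(clin$grade_ge3_lymphocyte_elevation,
                                   levels = c(TRUE, FALSE)))
  out$lymphocyte_ge3_fisher_p <- fisher_exact(as.matrix(ae_tab))
  for (wk in c("w8", "w16")) {
    det <- qol_deterioration(0, clin[[paste0("qol_change_", wk)]])
    tab <- table(clin$arm, factor(det, levels = c(TRUE, FALSE)))
    out[[paste0("qol_deterioration_", wk)]] <- list(
      rate_by_arm = lapply(split(det, clin$arm), mean),
      fisher_p = fisher_exact(as.matrix(tab))
    )
  }

  # KRAS-stratified survival: per arm and combined
  kras <- factor(m$kras_status, levels = c("mutant", "wildtype"))
  for (ep in endpoints) {
    per_arm <- lapply(levels(clin$arm), function(a) {
      sel <- clin$arm == a & !is.na(kras)
      .safe_comparison(.surv_compare(clin[sel, ], ep, kras[sel],
                                     stratum[sel]))
    })
    names(per_arm) <- levels(clin$arm)
    sel <- !is.na(kras)
    per_arm$combined <- .safe_comparison(
      .surv_compare(clin[sel, ], ep, kras[sel], stratum[sel])
    )
    out[[paste0(ep, "_by_kras")]] <- per_arm
  }
  sel <- !is.na(kras)
  out$kras_arm_interaction_p <- cox_interaction_p(
    clin$os_months[sel], clin$os_event[sel], clin$arm[sel], kras[sel]
  )$p.value

  # CTF wildtype-vs-mutant comparison
  out$ctf_by_kras <- compare_ctf_by_kras(m[!is.na(m$ctf), , drop = FALSE])

  # CTF-filtered sensitivity analysis
  if (!is.null(ctf_threshold)) {
    keep <- !is.na(m$ctf) & apply_ctf_threshold(m$ctf, ctf_threshold)
    out$ctf_filtered <- c(
      list(threshold = ctf_threshold, n_retained = sum(keep),
           wt_frequency = mean(kras[keep] == "wildtype")),
      list(os_by_kras = .safe_comparison(
        .surv_compare(clin[keep, ], "os", kras[keep], stratum[keep])
      ))
    )
  }

  # KM curve coordinates per arm (primary endpoint) for plotting/report
  km_rows <- do.call(rbind, lapply(levels(clin$arm), function(a) {
    km <- km_estimate(clin$os_months[clin$arm == a],
                      clin$os_event[clin$arm == a])
    data.frame(arm = a, time = km$time, surv = km$surv)
  }))
  utils::write.csv(km_rows, file.path(out_dir, "km_os_by_arm.csv"),
                   row.names = FALSE)

  path <- file.path(out_dir, "analyses.json")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  .log_stage("analyze", "OS arm HR = %.2f; combined KRAS-wildtype HR = %s",
             out$os_by_arm$hr,
             if (is.null(out$os_by_kras$combined$hr)) "not estimable" else
               sprintf("%.2f", out$os_by_kras$combined$hr))
  invisible(path)
}

#' Report stage: human-readable run summary
#'
#' @param run_dir directory holding the earlier stages' outputs.
#' @return invisibly, the summary path.
#' @export
stage_report <- function(run_dir) {
  an <- jsonlite::read_json(file.path(run_dir, "analyses.json"))
  cal <- if (file.exists(file.path(run_dir, "calibration.json")))
    jsonlite::read_json(file.path(run_dir, "calibration.json")) else NULL
  lines <- c(
    "ctdnatrial run summary",
    sprintf("  patients analyzed        : %d", an$n),
    sprintf("  OS chemo_ici vs chemo    : HR %.2f (90%% CI %.2f-%.2f), log-rank p = %.3g",
            an$os_by_arm$hr, an$os_by_arm$ci90$lower, an$os_by_arm$ci90$upper,
            an$os_by_arm$logrank_p),
    sprintf("  ORR                      : %s",
            paste(sprintf("%s %.1f%%", names(an$response$orr),
                          100 * unlist(an$response$orr)), collapse = ", ")),
    sprintf("  DCR                      : %s",
            paste(sprintf("%s %.1f%%", names(an$response$dcr),
                          100 * unlist(an$response$dcr)), collapse = ", ")),
    if (is.null(an$os_by_kras$combined$hr))
      "  OS wildtype vs mutant    : not estimable" else
      sprintf("  OS wildtype vs mutant    : HR %.2f (90%% CI %.2f-%.2f) [combined]",
              an$os_by_kras$combined$hr, an$os_by_kras$combined$ci90$lower,
              an$os_by_kras$combined$ci90$upper),
    sprintf("  CTF wildtype vs mutant   : medians %.3g / %.3g, p = %.3g",
            an$ctf_by_kras$median_wildtype, an$ctf_by_kras$median_mutant,
            an$ctf_by_kras$p.value)
  )
  if (!is.null(cal)) {
    lines <- c(lines, sprintf(
      "  CTF threshold            : %.4g (wildtype %.1f%%, retained %d/%d)",
      cal$chosen_threshold, 100 * cal$wt_frequency_at_threshold,
      cal$n_retained, cal$n_calibration))
  }
  if (!is.null(an$ctf_filtered)) {
    lines <- c(lines, if (is.null(an$ctf_filtered$os_by_kras$hr))
      sprintf("  CTF-filtered OS (KRAS)   : not estimable, n = %d",
              an$ctf_filtered$n_retained) else
      sprintf("  CTF-filtered OS (KRAS)   : HR %.2f, n = %d",
              an$ctf_filtered$os_by_kras$hr, an$ctf_filtered$n_retained))
  }
  path <- file.path(run_dir, "summary.txt")
  writeLines(lines, path)
  .log_stage("report", "summary written to %s", path)
  invisible(path)
}

#' Run the full pipeline
#'
#' simulate -> metrics -> calibrate -> analyze -> report, all under one
#' configured seed with per-stage derived streams; a manifest with MD5
#' digests of every output file is written last. Stage failures abort
#' with the failing stage named.
#'
#' @param config a [simulation_config()], or a path to a YAML config
#'   accepted by [read_run_config()].
#' @param out_dir output directory.
#' @param target_ceiling,retention_floor calibration settings (ignored
#'   when \code{config} is a YAML path carrying its own).
#' @return invisibly, the manifest path.
#' @export
run_pipeline <- function(config, out_dir, target_ceiling = 0.13,
                         retention_floor = 0.5) {
  if (is.character(config)) {
    rc <- read_run_config(config)
    target_ceiling <- rc$calibration$target_ceiling
    retention_floor <- rc$calibration$retention_floor
    config <- rc$sim
  }
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  set.seed(derive_seed(config$seed, "simulate"))
  paths <- run_stage("simulate", stage_simulate(config, out_dir))
  set.seed(derive_seed(config$seed, "metrics"))
  metrics_path <- run_stage("metrics", stage_metrics(
    paths["variants"], out_dir, config$panel, truth_path = paths["truth"]
  ))
  set.seed(derive_seed(config$seed, "calibrate"))
  cal_path <- run_stage("calibrate", stage_calibrate(
    metrics_path, out_dir, target_ceiling, retention_floor
  ))
  threshold <- jsonlite::read_json(cal_path)$chosen_threshold
  set.seed(derive_seed(config$seed, "analyze"))
  run_stage("analyze", stage_analyze(
    paths["clinical"], metrics_path, out_dir, ctf_threshold = threshold
  ))
  run_stage("report", stage_report(out_dir))

  files <- setdiff(list.files(out_dir), "manifest.json")
  digests <- tools::md5sum(file.path(out_dir, files))
  names(digests) <- files
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(
      tool = "ctdnatrial",
      version = as.character(utils::packageVersion("ctdnatrial")),
      seed = config$seed,
      n_patients = config$n_patients,
      calibration = list(target_ceiling = target_ceiling,
                         retention_floor = retention_floor),
      timestamp = format(Sys.time(), tz = "UTC"),
      digests = as.list(digests)
    ),
    manifest_path, auto_unbox = TRUE, digits = NA
  )
  invisible(manifest_path)
}
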