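# ctdnatrial

Simulation and analysis of circulating-tumor-DNA (ctDNA) biomarkers in a
randomized two-arm metastatic pancreatic ductal adenocarcinoma (mPDAC)
trial setting.

Exploratory liquid-biopsy analyses in mPDAC trials reduce each patient's
plasma variant calls to a handful of per-sample metrics — blood tumor
mutational burden (bTMB), circulating tumor fraction (CTF), *KRAS*
mutation status — and then ask whether those metrics stratify survival.
Because *KRAS*-wildtype PDAC is rare (~10–15% of patients), an inflated
observed wildtype fraction is a warning sign that low-shedding tumors are
being misread as wildtype, and a CTF threshold must be calibrated to
filter them. Patient-level data from such trials are access-restricted,
so this package pairs the full analysis machinery with a tested synthetic
cohort generator that reproduces the statistical structure the analysis
assumes. It is aimed at trial statisticians and translational
bioinformaticians who want a reproducible, testable implementation of
this analysis pattern.

## The quantities at the core

* **CTF from allele fractions.** For a diploid genome with a heterozygous
  clonal somatic mutation, MAF = CTF / (2(1 − CTF) + CTF), so
  CTF = 2 / (1/MAF + 1). The per-sample estimate applies this to the
  maximum allele fraction among somatic, autosomal, non-copy-number-
  altered calls.
* **bTMB** = (somatic coding SNVs, synonymous included, outside the CHIP
  genes *DNMT3A*/*TET2*/*ASXL1*/*JAK2*) / 2.4 Mb effective panel.
* **Threshold calibration.** Scan the ascending observed CTF values;
  at each, drop samples below the threshold and recompute the
  *KRAS*-wildtype frequency; stop at the smallest threshold where that
  frequency falls to the expected population ceiling while retaining an
  acceptable fraction of samples.
* **Trial statistics.** Kaplan–Meier medians, log-rank and Cox hazard
  ratios (90% Wald CIs) stratified by ECOG × prior adjuvant therapy,
  Cochran–Mantel–Haenszel response comparison, Fisher exact tests,
  Wilcoxon rank-sum, and the Schoenfeld event-count design formula
  d = ⌈(z₁₋α/₂ + z₁₋β)² / (p₁p₂ (ln HR)²)⌉.

## Worked example

```r
library(ctdnatrial)

cfg    <- simulation_config(n_patients = 180, seed = 20260925)
cohort <- simulate_cohort(cfg)
cohort
#> Synthetic ctDNA trial cohort: 180 patients (chemo = 60, chemo_ici = 120), 2908 variant calls
#>   KRAS mutant (truth): 139 (77%); seed 20260925

metrics <- compute_sample_metrics(cohort$variants, cfg$panel,
                                  sample_ids = cohort$truth$patient_id)
land <- summarize_landscape(cohort$variants, metrics)
head(land$gene_frequency, 4)
#>     gene n_samples frequency
#> 1   KRAS       139 0.7722222
#> 2   TP53       118 0.6555556
#> 3 CDKN2A        36 0.2000000
#> 4 CTNNB1        27 0.1500000
round(land$btmb_summary, 2)
#>    min median    max
#>   0.83   3.75  61.67

calibrate_ctf_threshold(metrics, target_ceiling = 0.13, retention_floor = 0.5)
#> CTF threshold calibration
#>   chosen threshold : 0.01939 (CTF = 1.94%)
#>   retained samples : 128 / 180 (71.1%)
#>   wildtype freq    : 12.5% (ceiling 13.0%)

kras <- factor(metrics$kras_status, levels = c("mutant", "wildtype"))
stratified_cox(cohort$clinical$os_months, cohort$clinical$os_event, kras,
               stratum = interaction(cohort$clinical$ecog,
                                     cohort$clinical$prior_adjuvant))
#> Survival comparison (wildtype vs mutant)
#>   medians  : mutant = 7.6 mo, wildtype = 27.3 mo
#>   HR       : 0.29 (90% CI 0.19-0.43)
#>   log-rank : p = 7.8e-08
```

Reading the output: the cohort lands on the configured conditions (2:1
arms, 77% *KRAS*-mutant, bTMB median 3.75 mut/Mb); the raw wildtype
fraction (23%) is well above the 10–15% expected for PDAC, and the
calibration finds a CTF cutoff of ~1.9% at which the wildtype frequency
drops to 12.5% while keeping 71% of samples; wildtype status is strongly
protective (this 180-patient draw estimates HR 0.29 against a generating
hazard ratio of 0.40 — single-cohort estimates of a strong effect swing
this much at n = 180).

The full pipeline (simulate → metrics → calibrate → analyze → report,
with a digest manifest) runs as one call or from the shell:

```r
run_pipeline(cfg, "run1")            # writes CSV/VCF/JSON + summary.txt
```

```sh
Rscript inst/cli/ctdnatrial.R run --config config.yaml --out run1
```

Design arithmetic:

```r
schoenfeld_events(alpha = 0.10, power = 0.80, hr = 0.65, allocation = c(2, 1))
#> [1] 150
projected_median(8.5, 0.65)
#> [1] 13.1
```

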