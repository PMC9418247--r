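Package: ctdnatrial
Title: Simulation and Analysis of ctDNA Biomarkers in a Metastatic
    Pancreatic Cancer Trial
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for exploratory circulating tumor DNA (ctDNA) analysis
    in a randomized metastatic pancreatic ductal adenocarcinoma trial
    setting. Simulates a fully synthetic liquid-biopsy cohort (clinical
    covariates under 2:1 stratified block randomization, per-patient
    variant calls from a 600-gene / 2.4 Mb targeted panel, latent
    circulating tumor fraction, proportional-hazards survival); computes
    per-sample ctDNA metrics (blood tumor mutational burden with
    CHIP-gene exclusion, circulating tumor fraction from mutant allele
    fractions, KRAS mutation status); calibrates a prevalence-targeted
    circulating-tumor-fraction threshold that excludes putative
    low-shedding samples; and runs the trial's statistical procedures
    (Kaplan-Meier, stratified log-rank and Cox, Cochran-Mantel-Haenszel,
    Fisher exact, Wilcoxon rank-sum, Schoenfeld event-count design
    arithmetic and power simulation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
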