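---
title: "Methods: simulating and analyzing ctDNA biomarkers in a two-arm mPDAC trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing ctDNA biomarkers in a two-arm mPDAC trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnatrial)
```

# Scope and model

`ctdnatrial` implements an exploratory circulating-tumor-DNA (ctDNA) analysis
for a randomized two-arm trial in metastatic pancreatic ductal adenocarcinoma
(mPDAC). Patient-level data from such trials are access-restricted, so the
package pairs the analysis machinery with a synthetic cohort generator that
reproduces the statistical structure the analysis assumes. The pipeline runs
in four stages:

1. **simulate** — draw a cohort (clinical covariates, latent tumor biology,
   per-patient variant calls, survival endpoints);
2. **metrics** — reduce each patient's variant calls to per-sample ctDNA
   metrics (bTMB, circulating tumor fraction, *KRAS* status);
3. **calibrate** — search for a circulating-tumor-fraction threshold at which
   the *KRAS*-wildtype frequency falls to its expected population value;
4. **analyze** — run the trial's survival and categorical statistics.

## Circulating tumor fraction from allele fractions

For a diploid tumor genome carrying a heterozygous clonal somatic mutation,
a sample whose cell-free DNA is a fraction $f$ tumor-derived shows that
mutation at allele fraction

$$\mathrm{MAF} = \frac{f}{2(1-f) + f}, \qquad\text{equivalently}\qquad
f = \frac{2}{1/\mathrm{MAF} + 1}.$$

`maf_to_ctf()` and `ctf_to_maf()` are exact inverses of one another (tested
to $10^{-12}$). The per-sample estimator `estimate_sample_ctf()` applies the
forward formula to an aggregate of the **eligible** allele fractions: somatic
calls on autosomes whose gene has no detectable copy-number change (a CNA
distorts the diploid assumption; sex chromosomes break the factor 2). The
aggregate is the **maximum** eligible MAF: the most clonal variant best
reflects tumor content, and subclonal variants only underestimate it. The
mean is available (`aggregate = "mean"`) for sensitivity analysis, since
vendor pipelines do not publish their aggregate. A sample with no eligible
variant has a missing CTF — it cannot be placed relative to any threshold
and is excluded (and flagged) during calibration.

## Blood tumor mutational burden

`compute_btmb()` counts somatic **coding single-nucleotide variants,
synonymous included**; indels and germline calls never count. Calls in the
four clonal-hematopoiesis (CHIP) genes *DNMT3A*, *TET2*, *ASXL1* and *JAK2*
are excluded, because hematopoietic clones contaminate plasma and would
inflate a tumor burden estimate. The count is normalized by the effective
coding panel size (default 2.4 Mb, a 600-gene liquid-biopsy panel). A sample
with zero eligible SNVs has bTMB 0, not missing — an assayed sample with no
detected SNV is a measurement, not a failure.

## KRAS status and the mutation landscape

A sample is *KRAS*-mutant iff it has at least one **somatic** *KRAS* call in
a loss-of-function effect class (frameshift, in-frame indel, nonsense,
missense). Synonymous and germline *KRAS* calls do not count. The landscape
summary (`summarize_landscape()`) reports, per gene, the fraction of samples
with at least one somatic loss-of-function call, plus per-sample counts and
the bTMB min/median/max.

## CTF threshold calibration

*KRAS*-wildtype PDAC is expected in roughly 10–15% of patients; a
substantially higher observed wildtype fraction suggests that low-shedding
tumors (low CTF) are being misread as wildtype. `calibrate_ctf_threshold()`
formalizes the iterative threshold search: candidate thresholds are the
ascending distinct observed CTF values (the search is data-driven, not a
fixed grid — any threshold between two observed values produces the same
partition as the larger observed value, so the observed values are the
complete set of distinct partitions); at each candidate, samples with CTF
below the threshold are excluded and the wildtype frequency among the
retained samples is recomputed. The chosen threshold is the smallest
candidate with wildtype frequency at or below `target_ceiling` while
retaining at least `retention_floor` of the samples. Ties at the threshold
are retained ("less than the threshold" is excluded). The stopping rule is
deliberately explicit configuration: a published analysis of this kind
targeted "approximately 10%" and stopped near 12.7% while keeping most
patients, so the defaults are `target_ceiling = 0.13` and
`retention_floor = 0.5`, both logged with every run rather than hidden as
constants. Both monotonicity properties (retained n non-increasing along the
trajectory; relaxing the ceiling never raises the chosen threshold) are
tested against a naive-loop oracle.

## Trial statistics

Survival estimation and comparison delegate to the `survival` package behind
a thin layer that fixes the trial's conventions:

* `km_estimate()` — product-limit estimator; the median is the smallest
  observed time with $S(t) \le 0.5$ and is reported as not-reached (never
  extrapolated) when the curve stays above 0.5.
* `stratified_logrank()` — observed-minus-expected and hypergeometric
  variances accumulated within stratum (ECOG × prior adjuvant therapy),
  pooled into a 1-df chi-square.
* `stratified_cox()` — stratified partial likelihood for one binary
  covariate, **Efron** tie handling by default (the simulator's monthly-scale
  granularity produces ties; Efron is more accurate there; Breslow is a
  flag). Hazard ratios are reported with **Wald 90% confidence intervals**
  on the log-HR scale, the trial's reporting convention. A monotone partial
  likelihood (complete separation) raises an error instead of returning a
  meaningless number; pipeline subgroup analyses record that error
  explicitly in the output JSON.
* `cmh_response_test()` — Mantel–Haenszel pooled odds ratio with a
  Robins–Breslow–Greenland interval and the CMH chi-square (no continuity
  correction), implemented directly from the closed forms because the base-R
  routine declines single-stratum input; it is cross-checked against
  `mantelhaen.test()` for $K \ge 2$.
* `fisher_exact()` — two-sided exact p by the minimum-likelihood convention
  (sum of hypergeometric outcomes with point probability at most the
  observed), which is what `fisher.test()` computes; stated explicitly
  because two-sided Fisher conventions differ between packages.
* `wilcoxon_ranksum()` — exact null distribution when the combined sample
  size is at most 12 with no ties, otherwise normal approximation with tie
  and continuity correction; the branch taken is returned with the result.
* `orr_dcr()` — response (CR+PR) and disease-control (CR+PR+SD) proportions
  with **all randomized patients** in the denominator; NE stays in.
* `qol_deterioration()` — deterioration iff the change from baseline is
  −10 points or lower on the 0–100 scale.
* `cox_interaction_p()` — the treatment-by-marker predictiveness check is a
  Wald test on the product term of an unstratified Cox model; the published
  analysis does not state its interaction method, so this standard choice is
  flagged as an assumption.

## Design arithmetic and power

`schoenfeld_events()` evaluates
$d = \lceil (z_{1-\alpha/2} + z_{1-\beta})^2 / (p_1 p_2 (\ln \mathrm{HR})^2) \rceil$;
with two-sided $\alpha = 0.10$, power 0.80, HR 0.65 and 2:1 allocation
($p_1 p_2 = 2/9$) this gives 150 deaths. Under exponential proportional
hazards a hazard ratio scales the median by its inverse, so a control median
of 8.5 months projects to $8.5/0.65 = 13.1$ months
(`projected_median()`). `power_by_simulation()` checks the design
empirically: exponential survival per arm, uniform accrual, analysis
triggered at the required event count, two-sided log-rank at $\alpha$. The
Schoenfeld count is a first-order approximation; at 150 events the exact
power of the event-driven analysis is close to one point above the nominal
80% (measured at ≈81.3% with 20,000 replicates), which is the expected
direction and size of the approximation error, not a bug in either formula
or simulation.

# The synthetic cohort generator

`simulate_cohort()` is first-class, tested code, not a test fixture. Its
defaults are the study conditions of the emulated trial; each is a single
choice documented here and not revisited.

**Clinical covariates.** 180 patients; ECOG 1 with probability 0.77 and
prior adjuvant chemotherapy with probability 0.11 (the covariate mix of the
emulated cohort); 2:1 allocation by stratified permuted blocks within
ECOG × prior-adjuvant strata. The real trial used dynamic minimization;
permuted blocks give the same marginal balance with a simpler, exactly
reproducible mechanism. Partial final blocks are filled from a pooled
remainder so the cohort-level totals match the target allocation exactly
(120:60 at n = 180) while within-stratum imbalance stays below one block.

**Latent tumor biology.** *KRAS* is somatically mutated with probability
0.77; *TP53*, *CDKN2A* and *SMAD4* at 0.65/0.22/0.13. The latent circulating
tumor fraction is log-normal within *KRAS* group — wildtype location
$\log(0.012)$, mutant location $\log(0.045)$, both with scale 1.0 — values a
liquid-biopsy analyst would call realistic for mPDAC (typical CTFs of a few
percent, heavy right tail, wildtype shedding several-fold lower, which is
the mechanism the threshold calibration exists to counteract). Draws at or
above 0.95 are resampled so CTF stays in (0, 1). Microsatellite instability
occurs with probability 1/173 and is carried as pass-through metadata (no
MSI caller is implemented); MSI patients receive an inflated somatic SNV
count targeting a reference bTMB of 52.9 mut/Mb.

**Variant calls.** Somatic loss-of-function counts are $1 +$ Poisson(4.2)
(median 5, minimum 1); mutated driver genes contribute one call each and
passengers fill the remainder. Germline loss-of-function counts follow the
same law over a pool of cancer-predisposition genes, with allele fractions
in the heterozygous band (0.45–0.55) or, with probability 0.1, the
homozygous band (≥ 0.97). Somatic synonymous SNVs (Poisson, rate 5) count
toward bTMB only; with the ~75% SNV share of the loss-of-function calls this
puts the cohort bTMB median near 3.7 mut/Mb, the value reported for the
emulated assay. Somatic allele fractions are
`ctf_to_maf(true_ctf)` × a clonal factor ~ Uniform(0.3, 1); one designated
autosomal, non-CNA variant per patient (the *KRAS* driver when present) has
factor exactly 1, which makes the maximum-MAF CTF estimator recover the
latent truth exactly — an identifiability guarantee the parameter-recovery
tests rely on. Ten percent of patients carry one incidental CHIP-gene call
at low, CTF-independent allele fraction (0.2–2%); other somatic calls carry
a 5% copy-number flag. Gene positions come from a bundled
gene-to-chromosome lookup (*KRAS* on chromosome 12, so CTF-eligible).

**Endpoints.** Overall survival is exponential within covariate cell:
hazard $\ln 2 / 8.5 \cdot \mathrm{hr}_{\text{arm}}^{[\text{exp}]} \cdot
\mathrm{hr}_{\text{KRASwt}}^{[\text{wt}]}$ per month. The exponential choice
is what the design arithmetic (median ratio = inverse hazard ratio)
presumes. Defaults are a null arm effect ($\mathrm{hr}_{\text{arm}} = 1$,
matching the emulated trial's negative primary result; 0.65 reproduces the
design scenario) and a protective wildtype effect of 0.40. PFS is OS times
a Beta(5, 4) fraction (no joint model is published; this keeps PFS ≤ OS
with a median PFS/OS ratio ≈ 0.56, matching the observed 5.5/9.8-month
pattern). Entry is uniform over a 23-month accrual window with
administrative censoring at 40 months from study start — at these values a
default cohort yields ≈150 observed deaths, the design's analysis trigger.
Best response is multinomial per arm, calibrated to objective response
rates of ~30% vs ~23% and disease-control rates of ~70% vs ~57% (the
published arm-level rates); the CR:PR split within the responder category
is not published and is set to a small CR share (2% vs 1%) — any such split
is arbitrary and only ORR/DCR are consumed downstream. QoL change scores
are Normal(−5, 15) in both arms (only the −10-point deterioration rule is
consumed); grade ≥ 3 lymphocyte elevation is Bernoulli (0.38 vs 0.20).

**What the generator does not emulate.** No read-level data, sequencing
error, or background-filtering artifacts; origin labels (somatic/germline)
are exact rather than inferred; effect classes are taken as given; tumor
shedding is a single latent scalar rather than a mixture of clones; no
dropout or loss to follow-up beyond administrative censoring. Passing tests
therefore demonstrate that the analysis machinery is correct and that the
procedures behave as designed **under their own assumptions** — not that
they are robust to variant-calling noise or model misspecification in real
cohorts.

# Numerical choices and degenerate inputs

* MAF = 0 maps to CTF 0 (the formula's limit); out-of-range fractions are
  rejected, not clamped.
* Calibration requires at least one mutant sample; an all-wildtype input is
  a "degenerate" error, and a search that exhausts the retention floor
  before reaching the ceiling is "no qualifying threshold" — both are
  errors, never silently returned thresholds.
* Cox fits are declared inestimable when the coefficient or its standard
  error diverges (|β| > 15 or SE > 100 on the log scale), the signature of
  a monotone likelihood.
* All randomness flows from one configured seed; pipeline stages derive
  per-stage seeds (`seed × 7919 + hash(stage) mod 2³¹−1`) so stages rerun
  independently yet deterministically, and two runs with the same seed
  produce byte-identical outputs (tested via the manifest's MD5 digests).
* Problem sizes used by the test suite: parameter recovery at n = 5,000
  (gene prevalences, 3-SE binomial bands) and n = 2,000 (wildtype hazard
  ratio 0.40 recovered within [0.32, 0.50]); design power at 2,000–3,000
  replicated trials (binomial SE ≈ 0.7–0.9 points). These sizes make the
  Monte-Carlo error small relative to each test's acceptance band.

# Known limitations

* The CTF estimator's diploid-heterozygous assumption is violated by copy
  gains even below the CNA-flag detection limit; the real vendor pipeline's
  aggregate is unpublished, so agreement with any specific vendor's CTF is
  not claimed.
* The germline/somatic origin heuristic (`infer_origin()`) is a crude
  allele-fraction band rule for unlabeled input only; it misclassifies
  high-CTF clonal somatic variants whose MAF drifts into the 0.40–0.60
  band.
* The calibration threshold is a data-driven statistic of the cohort; on
  synthetic cohorts it will not equal any particular published threshold
  value, and the procedure — not a number — is the reproducible artifact.
* The power simulation analyzes exactly at the event count with no dropout
  or accrual inflation, the simplest reading of an event-driven design.
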