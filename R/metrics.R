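# Per-sample ctDNA metrics: loss-of-function filtering, bTMB, circulating
# tumor fraction, KRAS status, mutation-landscape summaries.

#' Effect classes counted as loss-of-function
#' @keywords internal
lof_effects <- c("frameshift", "inframe_indel", "nonsense", "missense")

#' Closed vocabulary of variant effect classes
#' @keywords internal
effect_vocabulary <- c(lof_effects, "synonymous", "other")

.variant_columns <- c(
  "sample_id", "chrom", "pos", "ref", "alt", "gene", "effect",
  "is_snv", "is_coding", "allele_fraction", "origin", "cna_flag"
)

#' Validate a variant-call table
#'
#' Checks the column contract used throughout the package (one row per
#' called variant) and normalizes effect classes: values outside the
#' closed vocabulary are mapped to \code{"other"} with a warning.
#'
#' @param variants data.frame of variant calls.
#' @return the validated (possibly effect-normalized) data.frame.
#' @export
validate_variants <- function(variants) {
  if (!is.data.frame(variants)) stop("variants must be a data.frame")
  missing_cols <- setdiff(.variant_columns, names(variants))
  if (length(missing_cols) > 0) {
    stop("variant table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(variants) == 0) return(variants)
  if (any(variants$allele_fraction < 0 | variants$allele_fraction > 1, na.rm = TRUE)) {
    stop("allele_fraction must lie in [0, 1]")
  }
  if (any(variants$pos < 1, na.rm = TRUE)) stop("pos must be >= 1 (1-based)")
  if (!all(variants$origin %in% c("somatic", "germline"))) {
    stop("origin must be 'somatic' or 'germline'")
  }
  unknown <- !(variants$effect %in% effect_vocabulary)
  if (any(unknown)) {
    warning(sum(unknown), " variant(s) with unknown effect class mapped to 'other'")
    variants$effect[unknown] <- "other"
  }
  variants
}

#' Panel specification for bTMB computation
#'
#' @param effective_coding_size_mb effective targeted coding size in
#'   megabases used to normalize the somatic SNV count (default 2.4, the
#'   footprint of a 600-gene liquid-biopsy panel).
#' @param chip_genes genes whose variants are treated as likely clonal
#'   hematopoiesis (CHIP) and excluded from bTMB.
#' @return an object of class \code{panel_spec}.
#' @export
panel_spec <- function(effective_coding_size_mb = 2.4,
                       chip_genes = c("DNMT3A", "TET2", "ASXL1", "JAK2")) {
  if (!is.numeric(effective_coding_size_mb) || effective_coding_size_mb <= 0) {
    stop("effective_coding_size_mb must be a positive number")
  }
  structure(
    list(effective_coding_size_mb = effective_coding_size_mb,
         chip_genes = as.character(chip_genes)),
    class = "panel_spec"
  )
}

#' Retain loss-of-function variants
#'
#' Keeps frameshift, in-frame indel, nonsense and missense calls, in the
#' original order; all other effect classes (synonymous, other) drop out.
#'
#' @param variants variant-call data.frame.
#' @return the subset of rows with a loss-of-function effect class.
#' @export
filter_lof <- function(variants) {
  variants[variants$effect %in% lof_effects, , drop = FALSE]
}

#' Blood tumor mutational burden (bTMB)
#'
#' Counts somatic coding single-nucleotide variants (synonymous included,
#' indels and germline calls never counted), excludes CHIP-gene variants,
#' and normalizes by the effective coding panel size. A sample with no
#' eligible SNV has bTMB 0, not missing.
#'
#' @param variants variant-call data.frame for one sample (or any set of
#'   calls to be counted together).
#' @param panel a [panel_spec()].
#' @return bTMB in mutations per megabase.
#' @export
compute_btmb <- function(variants, panel = panel_spec()) {
  stopifnot(inherits(panel, "panel_spec"))
  if (nrow(variants) == 0) return(0)
  eligible <- variants$origin == "somatic" &
    variants$is_snv &
    variants$is_coding &
    !(variants$gene %in% panel$chip_genes)
  sum(eligible) / panel$effective_coding_size_mb
}

#' Estimate the circulating tumor fraction of one sample
#'
#' CTF is estimated from the allele fractions of autosomal somatic
#' mutations; calls in genes with a detectable copy-number change are
#' omitted (their allele fractions are distorted by the CNA). The default
#' aggregate is the maximum eligible allele fraction -- the most clonal
#' variant best reflects tumor content; the mean is available for
#' sensitivity analysis.
#'
#' @param variants variant-call data.frame; all rows must share one
#'   \code{sample_id}.
#' @param aggregate \code{"max"} (default) or \code{"mean"}.
#' @return CTF in \[0, 1\], or \code{NA_real_} when no eligible variant
#'   exists.
#' @export
estimate_sample_ctf <- function(variants, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  if (nrow(variants) > 0 && length(unique(variants$sample_id)) > 1) {
    stop("estimate_sample_ctf expects calls from a single sample_id")
  }
  autosomes <- as.character(1:22)
  eligible <- variants$origin == "somatic" &
    as.character(variants$chrom) %in% autosomes &
    !variants$cna_flag &
    !is.na(variants$allele_fraction)
  af <- variants$allele_fraction[eligible]
  if (length(af) == 0) return(NA_real_)
  maf <- switch(aggregate, max = max(af), mean = mean(af))
  maf_to_ctf(maf)
}

#' Call KRAS mutation status from a sample's variant calls
#'
#' A sample is KRAS-mutant iff it carries at least one somatic KRAS call
#' with a loss-of-function effect class (frameshift, in-frame indel,
#' nonsense or missense). Germline or synonymous KRAS calls do not
#' trigger mutant status.
#'
#' @param variants variant-call data.frame for one sample.
#' @return \code{"mutant"} or \code{"wildtype"}.
#' @export
call_kras_status <- function(variants) {
  hit <- variants$gene == "KRAS" &
    variants$origin == "somatic" &
    variants$effect %in% lof_effects
  if (any(hit)) "mutant" else "wildtype"
}

#' Heuristic somatic/germline origin inference for unlabeled calls
#'
#' Fallback for variant tables without an origin annotation: calls with
#' allele fraction in \[0.40, 0.60\] (heterozygous band) or >= 0.90
#' (homozygous band) are labeled germline, all others somatic. This is a
#' crude allele-fraction heuristic, not a validated germline filter; use
#' annotated origins whenever available.
#'
#' @param allele_fraction numeric vector.
#' @return character vector of \code{"somatic"} / \code{"germline"}.
#' @export
infer_origin <- function(allele_fraction) {
  ifelse((allele_fraction >= 0.40 & allele_fraction <= 0.60) |
           allele_fraction >= 0.90,
         "germline", "somatic")
}

#' Per-sample ctDNA metrics table
#'
#' Computes bTMB, CTF, KRAS status and loss-of-function variant counts for
#' every sample. Samples listed in \code{sample_ids} but absent from the
#' variant table get zero counts, bTMB 0 and missing CTF.
#'
#' @param variants variant-call data.frame for the whole cohort.
#' @param panel a [panel_spec()].
#' @param msi_status optional named character vector (\code{"MSI"}/\code{"MSS"})
#'   keyed by sample id; microsatellite status is assay metadata passed
#'   through, not called from the variants. Unlisted samples get \code{"MSS"}.
#' @param sample_ids optional full roster of sample ids (defaults to the
#'   ids present in \code{variants}).
#' @param ctf_aggregate passed to [estimate_sample_ctf()].
#' @return data.frame with one row per sample: \code{sample_id},
#'   \code{btmb}, \code{ctf}, \code{kras_status}, \code{msi_status},
#'   \code{n_lof_somatic}, \code{n_lof_germline}.
#' @export
compute_sample_metrics <- function(variants, panel = panel_spec(),
                                   msi_status = NULL, sample_ids = NULL,
                                   ctf_aggregate = "max") {
  variants <- validate_variants(variants)
  if (is.null(sample_ids)) sample_ids <- sort(unique(variants$sample_id))
  if (length(sample_ids) == 0) stop("empty cohort: no samples")
  rows <- lapply(sample_ids, function(id) {
    v <- variants[variants$sample_id == id, , drop = FALSE]
    lof <- filter_lof(v)
    data.frame(
      sample_id = id,
      btmb = compute_btmb(v, panel),
      ctf = estimate_sample_ctf(v, aggregate = ctf_aggregate),
      kras_status = call_kras_status(v),
      msi_status = if (!is.null(msi_status) && id %in% names(msi_status))
        unname(msi_status[id]) else "MSS",
      n_lof_somatic = sum(lof$origin == "somatic"),
      n_lof_germline = sum(lof$origin == "germline"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Cohort mutation-landscape summary
#'
#' Gene-level somatic loss-of-function frequencies (fraction of samples
#' with at least one somatic LoF call in the gene), per-sample variant
#' counts, and the bTMB distribution summary (min / median / max).
#'
#' @param variants cohort variant-call data.frame.
#' @param metrics metrics table from [compute_sample_metrics()]; computed
#'   on the fly if \code{NULL}.
#' @param panel a [panel_spec()] (used only when \code{metrics} is NULL).
#' @return list with elements \code{gene_frequency} (data.frame gene,
#'   n_samples, frequency, sorted by frequency), \code{per_sample_counts},
#'   and \code{btmb_summary} (min, median, max).
#' @export
summarize_landscape <- function(variants, metrics = NULL, panel = panel_spec()) {
  variants <- validate_variants(variants)
  if (is.null(metrics)) metrics <- compute_sample_metrics(variants, panel)
  n <- nrow(metrics)
  if (n == 0) stop("empty cohort")
  som_lof <- filter_lof(variants)
  som_lof <- som_lof[som_lof$origin == "somatic", , drop = FALSE]
  hits <- unique(som_lof[, c("sample_id", "gene")])
  tab <- table(hits$gene)
  gene_frequency <- data.frame(
    gene = names(tab),
    n_samples = as.integer(tab),
    frequency = as.integer(tab) / n,
    stringsAsFactors = FALSE
  )
  gene_frequency <- gene_frequency[order(-gene_frequency$frequency,
                                         gene_frequency$gene), , drop = FALSE]
  rownames(gene_frequency) <- NULL
  counts <- metrics[, c("sample_id", "n_lof_somatic", "n_lof_germline")]
  list(
    gene_frequency = gene_frequency,
    per_sample_counts = counts,
    btmb_summary = c(min = min(metrics$btmb),
                     median = stats::median(metrics$btmb),
                     max = max(metrics$btmb))
  )
}
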