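# Variant-call serialization: VCF v4.2 with the package's INFO/FORMAT
# contract (INFO GENE, EFFECT, ORIGIN, CNA; per-sample FORMAT field AF),
# plus a plain delimited-table alternative.

.vcf_header <- function(sample_ids) {
  c(
    "##fileformat=VCFv4.2",
    "##source=ctdnatrial",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=EFFECT,Number=1,Type=String,Description="Effect class">',
    '##INFO=<ID=ORIGIN,Number=1,Type=String,Description="somatic or germline">',
    '##INFO=<ID=CNA,Number=1,Type=Integer,Description="Gene has detectable copy-number change (0/1)">',
    '##FORMAT=<ID=AF,Number=1,Type=Float,Description="Allele fraction">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", sample_ids), collapse = "\t")
  )
}

#' Write variant calls to VCF v4.2
#'
#' One record per call; gene, effect class, somatic/germline origin and
#' the copy-number flag travel in INFO, the allele fraction in the
#' per-sample FORMAT field AF (missing for non-carrying samples). With
#' \code{per_sample = TRUE}, one single-sample VCF per patient is written
#' into \code{path} (a directory) instead.
#'
#' @param variants variant-call data.frame.
#' @param path output file (or directory when \code{per_sample}).
#' @param per_sample write one file per sample instead of a multi-sample
#'   VCF.
#' @return invisibly, the path(s) written.
#' @export
write_variants_vcf <- function(variants, path, per_sample = FALSE) {
  variants <- validate_variants(variants)
  if (per_sample) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(sort(unique(variants$sample_id)), function(id) {
      f <- file.path(path, paste0(id, ".vcf"))
      write_variants_vcf(variants[variants$sample_id == id, , drop = FALSE], f)
      f
    }, character(1))
    return(invisible(paths))
  }
  samples <- sort(unique(variants$sample_id))
  ord <- order(match(variants$chrom, c(1:22, "X", "Y")), variants$pos)
  v <- variants[ord, , drop = FALSE]
  info <- sprintf("GENE=%s;EFFECT=%s;ORIGIN=%s;CNA=%d",
                  v$gene, v$effect, v$origin, as.integer(v$cna_flag))
  af_cols <- matrix(".", nrow = nrow(v), ncol = length(samples))
  col_idx <- match(v$sample_id, samples)
  af_cols[cbind(seq_len(nrow(v)), col_idx)] <- sprintf("%.6g", v$allele_fraction)
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info, "AF",
                sep = "\t")
  if (nrow(v) > 0) {
    body <- paste(body, apply(af_cols, 1, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(.vcf_header(samples), body), path)
  invisible(path)
}

#' Read variant calls from a VCF written with the package's contract
#'
#' Parses a (possibly multi-sample) VCF v4.2 via \pkg{vcfR}, validating
#' that the INFO keys GENE/EFFECT/ORIGIN/CNA and the FORMAT field AF are
#' declared. Panel calls are coding by construction, so \code{is_coding}
#' is TRUE on read.
#'
#' @param path VCF file path.
#' @return variant-call data.frame (see [validate_variants()]).
#' @export
read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt_ids <- vcfR::queryMETA(vcf, element = "FORMAT")
  if (!any(grepl("ID=AF", unlist(fmt_ids)))) {
    stop("VCF schema error: required FORMAT field 'AF' is not declared")
  }
  for (key in c("GENE", "EFFECT", "ORIGIN", "CNA")) {
    if (!any(grepl(paste0("ID=", key, "($|,)"),
                   unlist(vcfR::queryMETA(vcf, element = "INFO"))))) {
      stop("VCF schema error: required INFO key '", key, "' is not declared")
    }
  }
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  af <- vcfR::extract.gt(vcf, element = "AF", as.numeric = TRUE)
  if (is.null(dim(af))) af <- matrix(af, ncol = 1,
                                     dimnames = list(NULL, colnames(vcf@gt)[-1]))
  gene <- vcfR::extract.info(vcf, element = "GENE")
  effect <- vcfR::extract.info(vcf, element = "EFFECT")
  origin <- vcfR::extract.info(vcf, element = "ORIGIN")
  cna <- vcfR::extract.info(vcf, element = "CNA", as.numeric = TRUE)

  rows <- which(!is.na(af), arr.ind = TRUE)
  i <- rows[, 1]
  out <- data.frame(
    sample_id = colnames(af)[rows[, 2]],
    chrom = fix$CHROM[i],
    pos = as.integer(fix$POS[i]),
    ref = fix$REF[i],
    alt = fix$ALT[i],
    gene = gene[i],
    effect = effect[i],
    is_snv = nchar(fix$REF[i]) == 1 & nchar(fix$ALT[i]) == 1,
    is_coding = TRUE,
    allele_fraction = af[rows],
    origin = origin[i],
    cna_flag = cna[i] == 1,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$sample_id, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  validate_variants(out)
}

#' Read a delimited variant-call table
#'
#' CSV alternative to VCF input; the header must carry the full
#' variant-call column contract. Rows lacking an \code{origin} column can
#' be labeled with the [infer_origin()] heuristic via
#' \code{infer_missing_origin}.
#'
#' @param path CSV file path.
#' @param infer_missing_origin apply the allele-fraction heuristic when
#'   the origin column is absent.
#' @return validated variant-call data.frame.
#' @export
read_variant_table <- function(path, infer_missing_origin = FALSE) {
  v <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(chrom = "character"))
  if (!"origin" %in% names(v) && infer_missing_origin) {
    v$origin <- infer_origin(v$allele_fraction)
  }
  validate_variants(v)
}
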