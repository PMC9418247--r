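#' Convert a mutant allele fraction to a circulating tumor fraction
#'
#' In a diploid genome with a heterozygous clonal somatic mutation, the
#' mutant allele fraction (MAF) observed in cell-free DNA relates to the
#' circulating tumor fraction (CTF, the proportion of cfDNA derived from
#' tumor cells) as \code{MAF = CTF / (2 (1 - CTF) + CTF)}, hence
#' \code{CTF = 2 / (1/MAF + 1)}.
#'
#' @param maf numeric vector of allele fractions in \[0, 1\].
#' @return numeric vector of tumor fractions in \[0, 1\]; \code{maf = 0}
#'   maps to 0 (the limit).
#' @seealso [ctf_to_maf()] for the exact inverse.
#' @export
#' @examples
#' maf_to_ctf(0.5)   # 2/3
#' maf_to_ctf(0.25)  # 0.4
maf_to_ctf <- function(maf) {
  if (!is.numeric(maf)) stop("maf must be numeric")
  bad <- !is.na(maf) & (maf < 0 | maf > 1)
  if (any(bad)) stop("maf must lie in [0, 1]")
  ifelse(maf == 0, 0, 2 / (1 / maf + 1))
}

#' Convert a circulating tumor fraction to the expected clonal allele fraction
#'
#' Exact inverse of [maf_to_ctf()]: \code{MAF = CTF / (2 - CTF)}.
#'
#' @param ctf numeric vector of tumor fractions in \[0, 1\].
#' @return numeric vector of allele fractions in \[0, 1\].
#' @export
#' @examples
#' ctf_to_maf(2 / 3)  # 0.5
ctf_to_maf <- function(ctf) {
  if (!is.numeric(ctf)) stop("ctf must be numeric")
  bad <- !is.na(ctf) & (ctf < 0 | ctf > 1)
  if (any(bad)) stop("ctf must lie in [0, 1]")
  ctf / (2 - ctf)
}
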