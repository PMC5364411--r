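#' Construct a VariantTable
#'
#' @param chrom integer chromosome labels.
#' @param pos integer base-pair positions (1-based, strictly increasing
#'   within chromosome).
#' @param cm genetic-map positions in centiMorgans; defaults to `pos * 1e-6`
#'   (1 cM/Mb).
#' @param id variant identifiers; default `snp1 ... snpM`.
#' @param a1,a2 effect and other allele; default "A"/"G".
#' @param maf minor allele frequencies in (0, 0.5], or NA when unknown.
#' @return a [VariantTable-class].
#' @examples
#' vt <- VariantTable(chrom = rep(1L, 3), pos = c(100L, 200L, 300L))
#' nVariants(vt)
#' @export
VariantTable <- function(chrom, pos, cm = pos * 1e-6,
                         id = paste0("snp", seq_along(pos)),
                         a1 = rep("A", length(pos)),
                         a2 = rep("G", length(pos)),
                         maf = rep(NA_real_, length(pos))) {
  new("VariantTable", chrom = as.integer(chrom), pos = as.integer(pos),
      cm = as.numeric(cm), id = as.character(id), a1 = as.character(a1),
      a2 = as.character(a2), maf = as.numeric(maf))
}

#' Construct a GeneticArchitecture
#'
#' The defaults are the study conditions for the ALS/schizophrenia analysis:
#' liability-scale SNP heritabilities 0.082 and 0.23, genetic correlation
#' 0.143, lifetime risks 1/400 and 1/100, and 10% of variants causal.
#'
#' @param h2Liab1,h2Liab2 liability-scale SNP heritabilities.
#' @param rg genetic correlation.
#' @param K1,K2 lifetime risks.
#' @param propCausal fraction of causal variants.
#' @return a [GeneticArchitecture-class].
#' @export
GeneticArchitecture <- function(h2Liab1 = 0.082, h2Liab2 = 0.23, rg = 0.143,
                                K1 = 1 / 400, K2 = 1 / 100,
                                propCausal = 0.1) {
  new("GeneticArchitecture", h2Liab1 = h2Liab1, h2Liab2 = h2Liab2, rg = rg,
      K1 = K1, K2 = K2, propCausal = propCausal)
}

#' Construct a CohortDesign
#'
#' @param nCases1,nControls1,nCases2,nControls2 cohort sizes.
#' @param nSharedControls controls common to both cohorts.
#' @param nStrata number of population strata.
#' @param stratumFst Balding-Nichols differentiation parameter.
#' @return a [CohortDesign-class].
#' @export
CohortDesign <- function(nCases1, nControls1, nCases2 = 0L, nControls2 = 0L,
                         nSharedControls = 0L, nStrata = 1L,
                         stratumFst = 0) {
  new("CohortDesign", nCases1 = as.integer(nCases1),
      nControls1 = as.integer(nControls1), nCases2 = as.integer(nCases2),
      nControls2 = as.integer(nControls2),
      nSharedControls = as.integer(nSharedControls),
      nStrata = as.integer(nStrata), stratumFst = stratumFst)
}

#' Construct a SummaryStats object
#'
#' When `p` is omitted it is derived as `2 * pnorm(-|z|)`.
#'
#' @param variants a [VariantTable-class].
#' @param z per-variant z-scores.
#' @param n per-variant sample sizes (recycled if scalar).
#' @param p two-sided p-values; derived from `z` when omitted.
#' @param beta optional per-allele effect sizes (log odds ratios).
#' @return a [SummaryStats-class].
#' @export
SummaryStats <- function(variants, z, n, p = 2 * pnorm(-abs(z)),
                         beta = NULL) {
  if (length(n) == 1L) n <- rep(as.numeric(n), length(z))
  new("SummaryStats", variants = variants, z = as.numeric(z),
      p = as.numeric(p), n = as.numeric(n), beta = beta)
}

#' Construct a RiskAlleleSet
#'
#' @param id variant identifiers.
#' @param pControl,pCase control and case risk-allele frequencies.
#' @param riskAllele risk-allele labels; defaults to "A".
#' @return a [RiskAlleleSet-class].
#' @export
RiskAlleleSet <- function(id, pControl, pCase,
                          riskAllele = rep("A", length(id))) {
  new("RiskAlleleSet", id = as.character(id), riskAllele = riskAllele,
      pControl = as.numeric(pControl), pCase = as.numeric(pCase))
}
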