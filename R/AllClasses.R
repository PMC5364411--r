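#' @import methods
#' @importFrom stats pnorm qnorm dnorm rnorm runif rbinom rpois rgamma rbeta
#'   cor sd var integrate glm binomial coef vcov logLik prcomp pchisq
#'   complete.cases quantile rchisq qbinom pbinom setNames na.omit
#' @importFrom utils head tail
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Per-variant metadata table
#'
#' Holds the variant annotation shared by every stage of the pipeline:
#' chromosome, physical and genetic-map position, identifier, effect and
#' other allele, and minor allele frequency.  Positions are 1-based;
#' genetic-map positions are in centiMorgans.
#'
#' @slot chrom integer chromosome labels.
#' @slot pos integer base-pair coordinates, strictly increasing within a
#'   chromosome.
#' @slot cm numeric genetic-map positions (cM), non-decreasing within a
#'   chromosome.
#' @slot id character, unique variant identifiers.
#' @slot a1,a2 character, effect and other allele.
#' @slot maf numeric minor allele frequency in (0, 0.5]; may be NA when the
#'   table was read from a source that does not report frequencies.
#'
#' @seealso [VariantTable()] for the constructor.
#' @export
setClass("VariantTable",
  representation(chrom = "integer", pos = "integer", cm = "numeric",
                 id = "character", a1 = "character", a2 = "character",
                 maf = "numeric"))

setValidity("VariantTable", function(object) {
  n <- length(object@id)
  lens <- c(length(object@chrom), length(object@pos), length(object@cm),
            length(object@a1), length(object@a2), length(object@maf))
  if (any(lens != n)) return("all slots must have equal length")
  if (anyDuplicated(object@id)) return("variant ids must be unique")
  for (ch in unique(object@chrom)) {
    i <- object@chrom == ch
    if (is.unsorted(object@pos[i], strictly = TRUE))
      return("pos must be strictly increasing within chrom")
    if (is.unsorted(object@cm[i]))
      return("cm must be non-decreasing within chrom")
  }
  m <- object@maf[!is.na(object@maf)]
  if (any(m <= 0 | m > 0.5)) return("maf must lie in (0, 0.5]")
  TRUE
})

#' Haplotype reference panel with block LD structure
#'
#' A binary haplotype matrix (rows = haplotypes, columns = variants) plus the
#' half-open variant-index intervals delimiting the LD blocks from which it
#' was generated.  Across-block LD is zero by construction; within-block LD
#' decays with genetic-map distance.
#'
#' @slot variants a [VariantTable-class].
#' @slot haplotypes integer 0/1 matrix, haplotype x variant.
#' @slot blockBounds two-column integer matrix of half-open, 0-based
#'   variant-index intervals `[start, end)` partitioning the variants.
#' @export
setClass("HaplotypePanel",
  representation(variants = "VariantTable", haplotypes = "matrix",
                 blockBounds = "matrix"))

setValidity("HaplotypePanel", function(object) {
  M <- length(object@variants@id)
  if (ncol(object@haplotypes) != M)
    return("haplotype column count must equal variant count")
  f <- colMeans(object@haplotypes)
  if (any(f < 0.005 | f > 0.995))
    return("column allele frequencies must lie within [0.005, 0.995]")
  bb <- object@blockBounds
  if (ncol(bb) != 2) return("blockBounds must have two columns")
  if (bb[1, 1] != 0L || bb[nrow(bb), 2] != M ||
      (nrow(bb) > 1 && any(bb[-1, 1] != bb[-nrow(bb), 2])))
    return("blocks must partition the variant index range")
  TRUE
})

#' Generating (or assumed) bivariate genetic architecture
#'
#' Liability-scale SNP heritabilities for two traits, their genetic
#' correlation, lifetime risks (population prevalences) and the fraction of
#' causal variants.  The implied liability-scale genetic covariance is
#' `rhoG = rg * sqrt(h2Liab1 * h2Liab2)`.
#'
#' @slot h2Liab1,h2Liab2 liability-scale SNP heritabilities in \[0, 1\].
#' @slot rg genetic correlation in \[-1, 1\].
#' @slot K1,K2 lifetime risks in (0, 1).
#' @slot propCausal fraction of variants with nonzero effects, in (0, 1\].
#' @export
setClass("GeneticArchitecture",
  representation(h2Liab1 = "numeric", h2Liab2 = "numeric", rg = "numeric",
                 K1 = "numeric", K2 = "numeric", propCausal = "numeric"))

setValidity("GeneticArchitecture", function(object) {
  with_slots <- c(object@h2Liab1, object@h2Liab2)
  if (any(with_slots < 0 | with_slots > 1)) return("h2 must lie in [0, 1]")
  if (abs(object@rg) > 1) return("rg must lie in [-1, 1]")
  if (object@K1 <= 0 || object@K1 >= 1 || object@K2 <= 0 || object@K2 >= 1)
    return("lifetime risks must lie in (0, 1)")
  if (object@propCausal <= 0 || object@propCausal > 1)
    return("propCausal must lie in (0, 1]")
  rho <- object@rg * sqrt(object@h2Liab1 * object@h2Liab2)
  if (rho^2 > object@h2Liab1 * object@h2Liab2 + 1e-12)
    return("implied per-variant effect covariance is not positive semi-definite")
  TRUE
})

#' Case-control cohort design for two traits with shared controls
#'
#' @slot nCases1,nControls1,nCases2,nControls2 cohort sizes.
#' @slot nSharedControls number of control individuals present in both
#'   cohorts; at most `min(nControls1, nControls2)`.
#' @slot nStrata number of population strata.
#' @slot stratumFst Balding-Nichols differentiation parameter controlling
#'   allele-frequency divergence among strata.
#' @export
setClass("CohortDesign",
  representation(nCases1 = "integer", nControls1 = "integer",
                 nCases2 = "integer", nControls2 = "integer",
                 nSharedControls = "integer", nStrata = "integer",
                 stratumFst = "numeric"))

setValidity("CohortDesign", function(object) {
  cnt <- c(object@nCases1, object@nControls1, object@nCases2,
           object@nControls2, object@nSharedControls)
  if (any(cnt < 0)) return("all counts must be non-negative")
  if (object@nSharedControls > min(object@nControls1, object@nControls2))
    return("nSharedControls must not exceed min(nControls1, nControls2)")
  if (object@nStrata < 1) return("nStrata must be >= 1")
  if (object@stratumFst < 0 || object@stratumFst >= 1)
    return("stratumFst must lie in [0, 1)")
  TRUE
})

#' Per-variant association summary statistics for one trait
#'
#' The lingua franca of the pipeline: per-variant z-score, two-sided
#' p-value and sample size, aligned 1:1 with a [VariantTable-class].
#' `p = 2 * pnorm(-|z|)` holds within floating tolerance.  The optional
#' `beta` slot carries per-allele effect sizes (log odds ratios) when known,
#' as needed for polygenic scoring.
#'
#' @slot variants a [VariantTable-class].
#' @slot z numeric z-scores.
#' @slot p numeric two-sided p-values.
#' @slot n numeric per-variant sample sizes (> 0).
#' @slot beta optional numeric per-allele effect sizes, or NULL.
#' @export
setClass("SummaryStats",
  representation(variants = "VariantTable", z = "numeric", p = "numeric",
                 n = "numeric", beta = "numericOrNULL"))

setValidity("SummaryStats", function(object) {
  M <- length(object@variants@id)
  if (length(object@z) != M || length(object@p) != M || length(object@n) != M)
    return("z, p, n must align 1:1 with variants")
  if (!is.null(object@beta) && length(object@beta) != M)
    return("beta must align 1:1 with variants")
  if (any(object@n <= 0)) return("n must be positive")
  ok <- is.na(object@z) | abs(object@p - 2 * pnorm(-abs(object@z))) < 1e-6
  if (!all(ok)) return("p must equal 2*pnorm(-|z|) within tolerance")
  TRUE
})

#' Per-variant LD scores
#'
#' `ell[j]` is the sum over variants within the window of the adjusted
#' squared correlation `r2 - (1 - r2)/(n - 2)` with variant j, including the
#' self term.
#'
#' @slot variants a [VariantTable-class] (the regression subset).
#' @slot ell numeric LD scores, aligned 1:1 with `variants`.
#' @slot nHaplotypes number of haplotypes the scores were estimated from.
#' @export
setClass("LDScoreTable",
  representation(variants = "VariantTable", ell = "numeric",
                 nHaplotypes = "integer"))

setValidity("LDScoreTable", function(object) {
  if (length(object@ell) != length(object@variants@id))
    return("ell must align 1:1 with variants")
  if (any(object@ell <= 0)) return("ell must be positive after flooring")
  TRUE
})

#' Univariate LD score regression fit
#'
#' @slot slope regression coefficient of chi-square on LD score.
#' @slot intercept regression intercept (exactly 1 when constrained).
#' @slot h2Obs observed-scale SNP heritability, `slope * M / mean(N)`.
#' @slot h2Liab liability-scale SNP heritability (NA when no prevalence was
#'   supplied).
#' @slot seH2 block-jackknife standard error of `h2Liab` (of `h2Obs` when no
#'   conversion was requested).
#' @slot meanChi2 mean chi-square over regression SNPs.
#' @slot nBlocks jackknife block count.
#' @slot constrained logical, intercept constrained to 1.
#' @slot M number of SNPs the heritability refers to.
#' @slot nMean mean GWAS sample size.
#' @export
setClass("LdscFit",
  representation(slope = "numeric", intercept = "numeric", h2Obs = "numeric",
                 h2Liab = "numeric", seH2 = "numeric", meanChi2 = "numeric",
                 nBlocks = "integer", constrained = "logical", M = "numeric",
                 nMean = "numeric"))

setValidity("LdscFit", function(object) {
  if (object@constrained && abs(object@intercept - 1) > 0)
    return("constrained fit must have intercept exactly 1")
  if (!is.na(object@seH2) && object@seH2 < 0) return("seH2 must be >= 0")
  TRUE
})

#' Bivariate LD score regression fit
#'
#' @slot rhoG genetic covariance (observed scale unless converted).
#' @slot rg genetic correlation `rhoG / sqrt(h2_1 * h2_2)`; may be NA when a
#'   component heritability is non-positive.
#' @slot seRg block-jackknife standard error of `rg`.
#' @slot pRg two-sided p-value from the normal approximation `rg / seRg`.
#' @slot crossIntercept intercept of the z1*z2 regression (sample-overlap
#'   term).
#' @slot fit1,fit2 the two component [LdscFit-class] objects.
#' @export
setClass("BivariateFit",
  representation(rhoG = "numeric", rg = "numeric", seRg = "numeric",
                 pRg = "numeric", crossIntercept = "numeric",
                 fit1 = "LdscFit", fit2 = "LdscFit"))

#' Bivariate liability-threshold comorbidity result
#'
#' @slot rhoLiab liability-scale covariance.
#' @slot t1,t2 liability thresholds.
#' @slot pJoint probability both liabilities exceed their threshold.
#' @slot recipJoint `1 / pJoint`.
#' @slot orComorbid odds ratio, with `orLo`/`orHi` the plug-in range from the
#'   genetic-correlation confidence bounds.
#' @slot orLo,orHi plug-in odds-ratio range (NA when no CI was supplied).
#' @slot nRequired required cohort size for the stated power, with
#'   `nRequiredLo`/`nRequiredHi` the plug-in range.
#' @slot nRequiredLo,nRequiredHi plug-in cohort-size range.
#' @slot misdiagnosisRate required misdiagnosis rate (NA when case counts
#'   were not supplied).
#' @export
setClass("ComorbidityResult",
  representation(rhoLiab = "numeric", t1 = "numeric", t2 = "numeric",
                 pJoint = "numeric", recipJoint = "numeric",
                 orComorbid = "numeric", orLo = "numeric", orHi = "numeric",
                 nRequired = "numeric", nRequiredLo = "numeric",
                 nRequiredHi = "numeric", misdiagnosisRate = "numeric"))

setValidity("ComorbidityResult", function(object) {
  if (abs(object@recipJoint * object@pJoint - 1) > 1e-8)
    return("recipJoint must be the reciprocal of pJoint")
  TRUE
})

#' Simulated case-control cohort with individual-level genotypes
#'
#' @slot genotypes integer dosage matrix, individual x variant.
#' @slot phenotype integer 0/1 case status.
#' @slot stratum integer stratum label per individual.
#' @slot liability numeric realized liabilities.
#' @slot geneticValue numeric realized genetic values.
#' @slot variants the [VariantTable-class] of the genotyped variants.
#' @slot sharedWith integer indices (into another cohort) of individuals that
#'   are literally shared, or empty.
#' @export
setClass("LiabilityCohort",
  representation(genotypes = "matrix", phenotype = "integer",
                 stratum = "integer", liability = "numeric",
                 geneticValue = "numeric", variants = "VariantTable",
                 sharedWith = "integer"))

setValidity("LiabilityCohort", function(object) {
  n <- nrow(object@genotypes)
  if (length(object@phenotype) != n || length(object@stratum) != n)
    return("phenotype and stratum must have one entry per individual")
  if (!all(object@phenotype %in% c(0L, 1L)))
    return("phenotype must be 0/1")
  if (ncol(object@genotypes) != length(object@variants@id))
    return("genotype columns must align with variants")
  TRUE
})

#' Independent risk-allele set for the heterogeneity test
#'
#' @slot id variant identifiers (pairwise independent in the panel).
#' @slot riskAllele the risk allele per variant.
#' @slot pControl control risk-allele frequency.
#' @slot pCase case risk-allele frequency (after orientation,
#'   `pCase >= pControl`).
#' @export
setClass("RiskAlleleSet",
  representation(id = "character", riskAllele = "character",
                 pControl = "numeric", pCase = "numeric"))

setValidity("RiskAlleleSet", function(object) {
  n <- length(object@id)
  if (length(object@pControl) != n || length(object@pCase) != n ||
      length(object@riskAllele) != n)
    return("all slots must have equal length")
  if (any(object@pControl <= 0 | object@pControl >= 1 |
          object@pCase <= 0 | object@pCase >= 1))
    return("allele frequencies must lie in (0, 1)")
  if (any(object@pCase < object@pControl - 1e-12))
    return("risk alleles must be oriented so that pCase >= pControl")
  TRUE
})
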