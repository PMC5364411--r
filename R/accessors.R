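#' @name accessors
#' @title Accessors for crosstrait data classes
#'
#' @description Accessor functions for the S4 containers: variant counts and
#' identifiers, haplotype matrices, z-scores, p-values, LD scores and fit
#' summaries.  Slots should be reached through these rather than `@`.
#'
#' @param x an object.
#' @return the requested component.
NULL

setGeneric("nVariants", function(x) standardGeneric("nVariants"))
setGeneric("variantIds", function(x) standardGeneric("variantIds"))
setGeneric("variants", function(x) standardGeneric("variants"))
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
setGeneric("blockBounds", function(x) standardGeneric("blockBounds"))
setGeneric("zScores", function(x) standardGeneric("zScores"))
setGeneric("pValues", function(x) standardGeneric("pValues"))
setGeneric("sampleSizes", function(x) standardGeneric("sampleSizes"))
setGeneric("effectSizes", function(x) standardGeneric("effectSizes"))
setGeneric("ldScores", function(x) standardGeneric("ldScores"))
setGeneric("h2Obs", function(x) standardGeneric("h2Obs"))
setGeneric("h2Liab", function(x) standardGeneric("h2Liab"))
setGeneric("rgEstimate", function(x) standardGeneric("rgEstimate"))
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname accessors
#' @export
setMethod("nVariants", "VariantTable", function(x) length(x@id))
#' @rdname accessors
#' @export
setMethod("nVariants", "HaplotypePanel", function(x) length(x@variants@id))
#' @rdname accessors
#' @export
setMethod("nVariants", "SummaryStats", function(x) length(x@variants@id))
#' @rdname accessors
#' @export
setMethod("variantIds", "VariantTable", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("variantIds", "HaplotypePanel", function(x) x@variants@id)
#' @rdname accessors
#' @export
setMethod("variantIds", "SummaryStats", function(x) x@variants@id)
#' @rdname accessors
#' @export
setMethod("variants", "HaplotypePanel", function(x) x@variants)
#' @rdname accessors
#' @export
setMethod("variants", "SummaryStats", function(x) x@variants)
#' @rdname accessors
#' @export
setMethod("variants", "LDScoreTable", function(x) x@variants)
#' @rdname accessors
#' @export
setMethod("variants", "LiabilityCohort", function(x) x@variants)
#' @rdname accessors
#' @export
setMethod("haplotypes", "HaplotypePanel", function(x) x@haplotypes)
#' @rdname accessors
#' @export
setMethod("blockBounds", "HaplotypePanel", function(x) x@blockBounds)
#' @rdname accessors
#' @export
setMethod("zScores", "SummaryStats", function(x) x@z)
#' @rdname accessors
#' @export
setMethod("pValues", "SummaryStats", function(x) x@p)
#' @rdname accessors
#' @export
setMethod("sampleSizes", "SummaryStats", function(x) x@n)
#' @rdname accessors
#' @export
setMethod("effectSizes", "SummaryStats", function(x) x@beta)
#' @rdname accessors
#' @export
setMethod("ldScores", "LDScoreTable", function(x) x@ell)
#' @rdname accessors
#' @export
setMethod("h2Obs", "LdscFit", function(x) x@h2Obs)
#' @rdname accessors
#' @export
setMethod("h2Liab", "LdscFit", function(x) x@h2Liab)
#' @rdname accessors
#' @export
setMethod("rgEstimate", "BivariateFit", function(x) x@rg)
#' @rdname accessors
#' @export
setMethod("genotypes", "LiabilityCohort", function(x) x@genotypes)
#' @rdname accessors
#' @export
setMethod("phenotype", "LiabilityCohort", function(x) x@phenotype)

#' Coerce a VariantTable to data.frame
#'
#' @param x a [VariantTable-class].
#' @param row.names,optional,... passed for generic consistency, ignored.
#' @return a data.frame with columns chrom, pos, cm, id, a1, a2, maf.
#' @export
as.data.frame.VariantTable <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  data.frame(chrom = x@chrom, pos = x@pos, cm = x@cm, id = x@id,
             a1 = x@a1, a2 = x@a2, maf = x@maf, stringsAsFactors = FALSE)
}

setMethod("show", "VariantTable", function(object) {
  cat("VariantTable with", length(object@id), "variants on",
      length(unique(object@chrom)), "chromosome(s)\n")
})

setMethod("show", "HaplotypePanel", function(object) {
  cat("HaplotypePanel:", nrow(object@haplotypes), "haplotypes x",
      ncol(object@haplotypes), "variants in", nrow(object@blockBounds),
      "LD blocks\n")
})

setMethod("show", "SummaryStats", function(object) {
  cat("SummaryStats for", length(object@z), "variants; mean chi2 =",
      signif(mean(object@z^2), 4), "; mean N =",
      signif(mean(object@n), 4), "\n")
})

setMethod("show", "GeneticArchitecture", function(object) {
  cat(sprintf(
    "GeneticArchitecture: h2_liab = (%.3g, %.3g), rg = %.3g, K = (%.4g, %.4g), propCausal = %.3g\n",
    object@h2Liab1, object@h2Liab2, object@rg, object@K1, object@K2,
    object@propCausal))
})

setMethod("show", "LDScoreTable", function(object) {
  cat("LDScoreTable for", length(object@ell), "variants; mean ell =",
      signif(mean(object@ell), 4), "\n")
})

setMethod("show", "LdscFit", function(object) {
  cat(sprintf(
    "LdscFit (%s intercept): h2_obs = %.4g, h2_liab = %.4g (SE %.3g), intercept = %.4g, mean chi2 = %.4g\n",
    if (object@constrained) "constrained" else "free",
    object@h2Obs, object@h2Liab, object@seH2, object@intercept,
    object@meanChi2))
})

setMethod("show", "BivariateFit", function(object) {
  cat(sprintf(
    "BivariateFit: rg = %.4g (SE %.3g, p = %.3g), rho_g = %.4g, cross-intercept = %.4g\n",
    object@rg, object@seRg, object@pRg, object@rhoG,
    object@crossIntercept))
})

setMethod("show", "ComorbidityResult", function(object) {
  cat(sprintf(
    "ComorbidityResult: rho_liab = %.4g; P(both) = %.4g (1 in %.0f); OR = %.3f",
    object@rhoLiab, object@pJoint, object@recipJoint, object@orComorbid))
  if (!is.na(object@orLo))
    cat(sprintf(" (%.3f-%.3f)", object@orLo, object@orHi))
  if (!is.na(object@nRequired))
    cat(sprintf("; required cohort n = %.0f", object@nRequired))
  cat("\n")
})

setMethod("show", "LiabilityCohort", function(object) {
  cat("LiabilityCohort:", sum(object@phenotype == 1L), "cases /",
      sum(object@phenotype == 0L), "controls x",
      ncol(object@genotypes), "variants;",
      length(unique(object@stratum)), "stratum(a)\n")
})

setMethod("show", "RiskAlleleSet", function(object) {
  cat("RiskAlleleSet with", length(object@id), "independent risk alleles\n")
})
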