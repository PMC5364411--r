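#' Build an independent risk-allele set from a discovery cohort
#'
#' Selects variants associated in the discovery (trait A) statistics,
#' prunes them to pairwise independence in the panel, orients each to its
#' risk allele (the allele enriched in cases), and records case and
#' control risk-allele frequencies from the discovery cohort.
#'
#' @param stats discovery [SummaryStats-class].
#' @param cohort discovery [LiabilityCohort-class] (for the frequencies).
#' @param panel [HaplotypePanel-class] for pruning.
#' @param pCut association p-value cutoff.
#' @param r2Max maximum pairwise r2 allowed between retained variants.
#' @return a [RiskAlleleSet-class]; the orientation (whether dosage must be
#'   flipped) is stored in the `"flip"` attribute of the id slot order via
#'   attribute `flip`.
#' @export
selectRiskAlleles <- function(stats, cohort, panel, pCut = 1e-3,
                              r2Max = 0.05) {
  cand <- which(stats@p < pCut)
  if (length(cand) < 2) stop("fewer than 2 risk variants pass the cutoff")
  cand <- cand[order(stats@p[cand])]
  X <- scale(panel@haplotypes)
  pid <- panel@variants@id
  keep <- integer(0)
  for (i in cand) {
    ci <- match(stats@variants@id[i], pid)
    if (is.na(ci)) next
    if (length(keep)) {
      cj <- match(stats@variants@id[keep], pid)
      r2 <- as.numeric(cor(X[, ci], X[, cj, drop = FALSE]))^2
      if (any(r2 > r2Max)) next
    }
    keep <- c(keep, i)
  }
  ids <- stats@variants@id[keep]
  G <- genotypes(cohort)
  colnames(G) <- variants(cohort)@id
  y <- phenotype(cohort)
  Gk <- G[, ids, drop = FALSE]
  fCase <- colMeans(Gk[y == 1L, , drop = FALSE]) / 2
  fCtrl <- colMeans(Gk[y == 0L, , drop = FALSE]) / 2
  flip <- fCase < fCtrl
  vt <- stats@variants
  ra <- ifelse(flip, vt@a2[keep], vt@a1[keep])
  pCase <- ifelse(flip, 1 - fCase, fCase)
  pCtrl <- ifelse(flip, 1 - fCtrl, fCtrl)
  ok <- pCtrl > 0 & pCtrl < 1 & pCase > 0 & pCase < 1
  rs <- RiskAlleleSet(ids[ok], pControl = pCtrl[ok], pCase = pCase[ok],
                      riskAllele = ra[ok])
  attr(rs@id, "flip") <- flip[ok]
  rs
}

#' Heterogeneity test for a contaminating case subgroup
#'
#' Tests whether a subset of trait-B cases carries correlated excess
#' trait-A risk alleles - the genetic signature of misdiagnosed
#' individuals.  Under pure pleiotropy (all cases share diluted risk
#' uniformly) the risk alleles stay uncorrelated in cases and the
#' statistic is null-calibrated; a contaminating subgroup induces positive
#' pairwise correlations.
#'
#' For all pairs (i, j) of independent risk alleles,
#' `y_ij = (r_case,ij - r_control,ij) * sqrt(Neff)` with
#' `Neff = 1 / (1/Ncase + 1/Ncontrol)`, and
#' `S = sum w_ij y_ij / sqrt(sum w_ij^2)` is standard normal under the
#' null.  The default weights are
#' `w_ij = delta_i delta_j / sqrt(p_i q_i p_j q_j)` with
#' `delta = pCase - pControl`; `weights = "or"` uses the odds-ratio
#' parameterization `w_ij = sqrt(p_i q_i p_j q_j) d_i d_j` with
#' `d = (gamma - 1) / ((gamma - 1) p + 1)`.
#'
#' @param caseGeno trait-B case dosage matrix (columns named by variant id
#'   or aligned with `riskSet`).
#' @param controlGeno control dosage matrix.
#' @param riskSet a [RiskAlleleSet-class]; dosages are oriented to the
#'   risk allele using its `flip` attribute when present.
#' @param weights "delta" (default) or "or".
#' @return a list with `S` (standard-normal statistic), `p` (one-sided),
#'   and `nVariants` used.
#' @export
buhmboxStatistic <- function(caseGeno, controlGeno, riskSet,
                             weights = c("delta", "or")) {
  weights <- match.arg(weights)
  ids <- riskSet@id
  if (length(ids) < 2) stop("need at least 2 risk variants")
  orient <- function(G) {
    if (!is.null(colnames(G))) G <- G[, ids, drop = FALSE]
    flip <- attr(riskSet@id, "flip")
    if (!is.null(flip)) G[, flip] <- 2 - G[, flip, drop = FALSE]
    G
  }
  Gc <- orient(caseGeno)
  Gt <- orient(controlGeno)
  poly <- apply(Gc, 2, var) > 0 & apply(Gt, 2, var) > 0
  if (!all(poly))
    message(sum(!poly), " monomorphic risk variant(s) dropped")
  Gc <- Gc[, poly, drop = FALSE]; Gt <- Gt[, poly, drop = FALSE]
  p <- riskSet@pControl[poly]
  delta <- riskSet@pCase[poly] - p
  m <- ncol(Gc)
  if (m < 2) stop("fewer than 2 polymorphic risk variants remain")
  rCase <- cor(Gc); rCtrl <- cor(Gt)
  nEff <- 1 / (1 / nrow(Gc) + 1 / nrow(Gt))
  Y <- (rCase - rCtrl) * sqrt(nEff)
  pq <- p * (1 - p)
  if (weights == "delta") {
    wv <- delta / sqrt(pq)
  } else {
    gamma <- (riskSet@pCase[poly] * (1 - p)) /
             (p * (1 - riskSet@pCase[poly]))
    wv <- sqrt(pq) * (gamma - 1) / ((gamma - 1) * p + 1)
  }
  W <- outer(wv, wv)
  ut <- upper.tri(W)
  S <- sum(W[ut] * Y[ut]) / sqrt(sum(W[ut]^2))
  list(S = S, p = pnorm(S, lower.tail = FALSE), nVariants = m)
}
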