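#' Residualize conditioning statistics on LD score
#'
#' Removes the polygenic (LD-proportional) component from the conditioning
#' trait's chi-square statistics by subtracting the product of each
#' variant's LD score and the univariate regression coefficient:
#' `chi2_resid = max(chi2 - slope * ell, 1e-8)`, with p-values recomputed
#' from the 1-df chi-square survival function.  Ranks within equal-ell
#' strata are preserved.  Variants without an LD score are dropped with a
#' logged count.
#'
#' @param stats conditioning-trait [SummaryStats-class].
#' @param scores an [LDScoreTable-class].
#' @param fit the [LdscFit-class] from the same stats/scores pairing.
#' @return a [SummaryStats-class] with residualized statistics.
#' @export
residualizeOnLdscore <- function(stats, scores, fit) {
  idx <- match(stats@variants@id, scores@variants@id)
  drop <- is.na(idx)
  if (any(drop))
    message(sum(drop), " variant(s) without an LD score dropped")
  keep <- which(!drop)
  ell <- scores@ell[idx[keep]]
  chi2 <- stats@z[keep]^2
  chi2r <- pmax(chi2 - fit@slope * ell, 1e-8)
  zr <- sign(stats@z[keep]) * sqrt(chi2r)
  SummaryStats(subsetVariants(stats@variants, keep), z = zr,
               n = stats@n[keep])
}

#' Decorrelate conditioning z-scores against shared-control overlap
#'
#' Removes the null correlation induced by sample overlap (for example
#' shared controls) from the conditioning trait's z-scores:
#' `z_adj = (z_cond - nullCorr * z_primary) / sqrt(1 - nullCorr^2)`.
#' With `nullCorr = 0` this is the identity.  `nullCorr` is typically
#' taken from the bivariate regression's cross-intercept or from the
#' design value [sharedControlNullCorr()].
#'
#' @param zPrimary,zConditioning aligned z-score vectors.
#' @param nullCorr null correlation, |nullCorr| < 1.
#' @return adjusted conditioning z-scores.
#' @export
sharedControlAdjust <- function(zPrimary, zConditioning, nullCorr) {
  if (abs(nullCorr) >= 1) stop("|nullCorr| must be < 1")
  (zConditioning - nullCorr * zPrimary) / sqrt(1 - nullCorr^2)
}


#' Conditional false discovery rate
#'
#' Empirical-cdf conditional FDR of a primary trait given a conditioning
#' trait: for each variant i,
#' `cfdr_i = p1_i * #{j: p2_j <= p2_i} / #{j: p1_j <= p1_i & p2_j <= p2_i}`,
#' with ties counted inclusively and the result clipped to
#' `[p1_i, 1]`.  The dominance counts are computed with a Fenwick tree in
#' O(M log M).
#'
#' @param pPrimary,pConditioning aligned p-value vectors in (0, 1].
#' @return per-variant cFDR values.
#' @export
conditionalFdr <- function(pPrimary, pConditioning) {
  M <- length(pPrimary)
  if (length(pConditioning) != M)
    stop("p-value vectors must have equal length")
  if (any(pPrimary <= 0 | pPrimary > 1 | pConditioning <= 0 |
          pConditioning > 1))
    stop("p-values must lie in (0, 1]")
  nCond <- rank(pConditioning, ties.method = "max")
  r1 <- match(pPrimary, sort(unique(pPrimary)))   # dense ranks
  ord <- order(pConditioning)
  # dominance counts via a Fenwick tree over the primary-p ranks; the
  # tree lives in this scope so subassignment stays in place
  nT <- max(r1)
  tree <- integer(nT)
  denom <- integer(M)
  i <- 1L
  while (i <= M) {
    # process a tie group of pConditioning together (inclusive ties)
    j <- i
    while (j < M && pConditioning[ord[j + 1L]] == pConditioning[ord[i]])
      j <- j + 1L
    for (k in i:j) {
      a <- r1[ord[k]]
      while (a <= nT) { tree[a] <- tree[a] + 1L; a <- a + bitwAnd(a, -a) }
    }
    for (k in i:j) {
      a <- r1[ord[k]]; s <- 0L
      while (a > 0L) { s <- s + tree[a]; a <- a - bitwAnd(a, -a) }
      denom[ord[k]] <- s
    }
    i <- j + 1L
  }
  cf <- pPrimary * nCond / denom
  pmin(pmax(cf, pPrimary), 1)
}

#' Clump significant cFDR variants into loci
#'
#' Greedy by ascending cFDR among sub-threshold variants: each lead
#' collects all remaining sub-threshold variants with `r2 > r2Cut` to it.
#'
#' @param cfdrValues per-variant cFDR, aligned with `vt`.
#' @param vt a [VariantTable-class].
#' @param panel [HaplotypePanel-class] supplying LD (columns matched by
#'   variant id).
#' @param r2Cut LD threshold for locus membership (default 0.1).
#' @param threshold cFDR significance threshold (default 0.01).
#' @return a data.frame with one row per locus: lead id, nMembers,
#'   minCfdr, plus a `members` list-column of member ids.
#' @export
clumpLoci <- function(cfdrValues, vt, panel, r2Cut = 0.1,
                      threshold = 0.01) {
  sub <- which(cfdrValues < threshold)
  if (!length(sub))
    return(data.frame(lead = character(0), nMembers = integer(0),
                      minCfdr = numeric(0)))
  X <- scale(panel@haplotypes)
  pid <- panel@variants@id
  sub <- sub[order(cfdrValues[sub], vt@chrom[sub], vt@pos[sub],
                   vt@id[sub])]
  taken <- logical(length(cfdrValues))
  loci <- list()
  for (i in sub) {
    if (taken[i]) next
    taken[i] <- TRUE
    cand <- sub[!taken[sub]]
    members <- vt@id[i]
    if (length(cand)) {
      ci <- match(vt@id[i], pid)
      cj <- match(vt@id[cand], pid)
      r2 <- as.numeric(cor(X[, ci], X[, cj, drop = FALSE]))^2
      hit <- cand[!is.na(r2) & r2 > r2Cut]
      taken[hit] <- TRUE
      members <- c(members, vt@id[hit])
    }
    loci[[length(loci) + 1L]] <-
      list(lead = vt@id[i], nMembers = length(members),
           minCfdr = cfdrValues[i], members = members)
  }
  out <- data.frame(lead = vapply(loci, `[[`, character(1), "lead"),
                    nMembers = vapply(loci, `[[`, integer(1), "nMembers"),
                    minCfdr = vapply(loci, `[[`, numeric(1), "minCfdr"))
  out$members <- lapply(loci, `[[`, "members")
  out
}
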