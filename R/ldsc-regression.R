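# Weighted least squares of y on ell with optional origin constraint,
# plus per-block sufficient statistics for the delete-one-block jackknife.
.ldscWls <- function(y, ell, w, block, constrained) {
  if (constrained) {
    sxy <- tapply(w * ell * y, block, sum)
    sxx <- tapply(w * ell * ell, block, sum)
    slope <- sum(sxy) / sum(sxx)
    del <- (sum(sxy) - sxy) / (sum(sxx) - sxx)
    list(slope = slope, intercept = 1,
         slopeDel = as.numeric(del), interceptDel = rep(1, length(del)))
  } else {
    s1 <- tapply(w, block, sum)
    sx <- tapply(w * ell, block, sum)
    sy <- tapply(w * y, block, sum)
    sxx <- tapply(w * ell * ell, block, sum)
    sxy <- tapply(w * ell * y, block, sum)
    solve2 <- function(a1, ax, ay, axx, axy) {
      det <- a1 * axx - ax^2
      c(int = (axx * ay - ax * axy) / det,
        slope = (a1 * axy - ax * ay) / det)
    }
    full <- solve2(sum(s1), sum(sx), sum(sy), sum(sxx), sum(sxy))
    B <- length(s1)
    dl <- vapply(seq_len(B), function(b)
      solve2(sum(s1) - s1[b], sum(sx) - sx[b], sum(sy) - sy[b],
             sum(sxx) - sxx[b], sum(sxy) - sxy[b]), numeric(2))
    list(slope = full["slope"], intercept = full["int"],
         slopeDel = dl[2, ], interceptDel = dl[1, ])
  }
}

.jackSe <- function(theta) {
  theta <- theta[is.finite(theta)]
  B <- length(theta)
  if (B < 2) return(NA_real_)
  sqrt((B - 1) / B * sum((theta - mean(theta))^2))
}

# Align two objects on shared variant ids (position order); flips z2 where
# effect/other alleles are swapped between the two tables.
.alignStats <- function(stats1, stats2) {
  ids <- intersect(stats1@variants@id, stats2@variants@id)
  i1 <- match(ids, stats1@variants@id)
  i2 <- match(ids, stats2@variants@id)
  flip <- stats1@variants@a1[i1] == stats2@variants@a2[i2] &
          stats1@variants@a2[i1] == stats2@variants@a1[i2]
  list(i1 = i1, i2 = i2, flip = flip)
}

.ldscPrep <- function(stats, scores, chi2MaxMult = 80) {
  ids <- intersect(stats@variants@id, scores@variants@id)
  is <- match(ids, stats@variants@id)
  il <- match(ids, scores@variants@id)
  ord <- order(stats@variants@chrom[is], stats@variants@pos[is])
  is <- is[ord]; il <- il[ord]
  chi2 <- stats@z[is]^2
  cap <- chi2MaxMult * mean(chi2)
  nW <- sum(chi2 > cap)
  if (nW > 0) {
    message(nW, " chi-square value(s) winsorized at ", signif(cap, 4))
    chi2 <- pmin(chi2, cap)
  }
  list(chi2 = chi2, z = stats@z[is], n = stats@n[is],
       ell = scores@ell[il], ids = ids[ord])
}

#' Univariate LD score regression
#'
#' Weighted least squares of per-variant chi-square on LD score over the
#' intersection of summary statistics and score table, following the model
#' `E[chi2_j] = a + (N h2 / M) ell_j`.  Weights combine the
#' over-counting term `1 / max(ell, 1)` with the heteroskedasticity term
#' `1 / (1 + N h2 ell / M)^2` and are iterated twice from an unweighted
#' pass.  In constrained mode the intercept is fixed at 1 (chi-square minus
#' one regressed through the origin).  Standard errors come from a
#' delete-one-block jackknife over contiguous variant blocks.
#'
#' @param stats a [SummaryStats-class].
#' @param scores an [LDScoreTable-class].
#' @param M number of SNPs the heritability refers to; defaults to the
#'   number of regression SNPs.
#' @param constrainedIntercept logical; fix the intercept at 1.
#' @param nBlocks jackknife block count (default 200).
#' @param K,P population prevalence and sample case fraction for
#'   liability-scale conversion; when omitted `h2Liab` is NA and the SE
#'   refers to the observed scale.
#' @param minVariants minimum shared variants required (default 200).
#' @return an [LdscFit-class].
#' @export
univariateLdsc <- function(stats, scores, M = NULL,
                           constrainedIntercept = FALSE, nBlocks = 200,
                           K = NULL, P = NULL, minVariants = 200) {
  d <- .ldscPrep(stats, scores)
  nv <- length(d$chi2)
  if (nv < minVariants)
    stop("need at least ", minVariants, " shared variants, have ", nv)
  if (nv < nBlocks) stop("fewer variants than jackknife blocks")
  if (is.null(M)) M <- nv
  if (M < nv) stop("M must be at least the number of regression variants")
  N <- mean(d$n)
  y <- if (constrainedIntercept) d$chi2 - 1 else d$chi2
  block <- ceiling(seq_along(y) / (nv / nBlocks))
  w <- rep(1, nv)
  fit <- NULL
  for (it in 1:3) {  # unweighted pass + two weight iterations
    fit <- .ldscWls(y, d$ell, w, block, constrainedIntercept)
    h2hat <- max(min(fit$slope * M / N, 1), 0)
    w <- 1 / pmax(d$ell, 1) / (1 + N * h2hat * d$ell / M)^2
  }
  h2o <- as.numeric(fit$slope * M / N)
  h2oDel <- fit$slopeDel * M / N
  fac <- if (!is.null(K) && !is.null(P)) liabilityFactor(K, P) else NA_real_
  h2l <- h2o * fac
  se <- if (is.na(fac)) .jackSe(h2oDel) else .jackSe(h2oDel * fac)
  new("LdscFit", slope = as.numeric(fit$slope),
      intercept = as.numeric(fit$intercept), h2Obs = h2o, h2Liab = h2l,
      seH2 = se, meanChi2 = mean(d$chi2), nBlocks = as.integer(nBlocks),
      constrained = constrainedIntercept, M = as.numeric(M), nMean = N)
}

#' Bivariate LD score regression
#'
#' Weighted regression of the per-variant z-score product on LD score with
#' a free intercept (the sample-overlap term), giving the genetic
#' covariance `rhoG = slope * M / sqrt(meanN1 * meanN2)`; the genetic
#' correlation divides by the component heritabilities, which are fitted on
#' the same variants.  Alleles are aligned across the two tables (z flipped
#' where effect and other allele are swapped).  The standard error and the
#' two-sided p-value of `rg` come from a delete-one-block jackknife of the
#' full `rg` statistic.
#'
#' @param stats1,stats2 [SummaryStats-class] for the two traits.
#' @param scores an [LDScoreTable-class].
#' @param M SNP count for the heritability scaling (defaults to the number
#'   of shared regression SNPs).
#' @param nBlocks jackknife block count.
#' @param constrained1,constrained2 intercept constraints for the two
#'   component heritability fits.
#' @param minVariants minimum shared variants (default 200).
#' @return a [BivariateFit-class].
#' @export
bivariateLdsc <- function(stats1, stats2, scores, M = NULL, nBlocks = 200,
                          constrained1 = FALSE, constrained2 = FALSE,
                          minVariants = 200) {
  al <- .alignStats(stats1, stats2)
  z2flip <- stats2@z[al$i2] * ifelse(al$flip, -1, 1)
  vt1 <- subsetVariants(stats1@variants, al$i1)
  s1 <- SummaryStats(vt1, z = stats1@z[al$i1], n = stats1@n[al$i1])
  s2 <- SummaryStats(vt1, z = z2flip, n = stats2@n[al$i2])

  fit1 <- univariateLdsc(s1, scores, M = M,
                         constrainedIntercept = constrained1,
                         nBlocks = nBlocks, minVariants = minVariants)
  fit2 <- univariateLdsc(s2, scores, M = M,
                         constrainedIntercept = constrained2,
                         nBlocks = nBlocks, minVariants = minVariants)

  ids <- intersect(vt1@id, scores@variants@id)
  is <- match(ids, vt1@id)
  il <- match(ids, scores@variants@id)
  ord <- order(vt1@chrom[is], vt1@pos[is])
  is <- is[ord]; il <- il[ord]
  z1 <- s1@z[is]; z2 <- s2@z[is]; ell <- scores@ell[il]
  nv <- length(z1)
  if (is.null(M)) M <- nv
  N1 <- mean(s1@n); N2 <- mean(s2@n)
  block <- ceiling(seq_len(nv) / (nv / nBlocks))

  y <- z1 * z2
  w <- rep(1, nv)
  fitC <- NULL
  for (it in 1:3) {
    fitC <- .ldscWls(y, ell, w, block, constrained = FALSE)
    rhoHat <- fitC$slope * M / sqrt(N1 * N2)
    w <- 1 / pmax(ell, 1) /
      ((1 + N1 * max(fit1@h2Obs, 0) * ell / M) *
       (1 + N2 * max(fit2@h2Obs, 0) * ell / M) +
       (sqrt(N1 * N2) * rhoHat * ell / M + fitC$intercept)^2)
  }
  rhoG <- as.numeric(fitC$slope * M / sqrt(N1 * N2))

  if (fit1@h2Obs <= 0 || fit2@h2Obs <= 0) {
    warning("a component heritability is non-positive; rg undefined")
    return(new("BivariateFit", rhoG = rhoG, rg = NA_real_, seRg = NA_real_,
               pRg = NA_real_,
               crossIntercept = as.numeric(fitC$intercept),
               fit1 = fit1, fit2 = fit2))
  }
  rgPoint <- rhoG / sqrt(fit1@h2Obs * fit2@h2Obs)
  # delete-block rg from the three regressions' delete-block slopes
  d1 <- .ldscDelSlopes(s1, scores, M, nBlocks, constrained1)
  d2 <- .ldscDelSlopes(s2, scores, M, nBlocks, constrained2)
  prod12 <- d1 * d2
  rgDel <- ifelse(prod12 > 0, fitC$slopeDel / sqrt(prod12), NA_real_)
  if (anyNA(rgDel))
    warning(sum(is.na(rgDel)),
            " jackknife block(s) with non-positive heritability dropped")
  seRg <- .jackSe(rgDel)
  if (!is.na(rgPoint) && abs(rgPoint) > 1)
    warning("|rg| exceeds 1 (estimation noise): ", signif(rgPoint, 4))
  pRg <- 2 * pnorm(-abs(rgPoint / seRg))
  new("BivariateFit", rhoG = rhoG, rg = as.numeric(rgPoint),
      seRg = seRg, pRg = as.numeric(pRg),
      crossIntercept = as.numeric(fitC$intercept), fit1 = fit1, fit2 = fit2)
}

# Delete-block slopes of a univariate fit, replicating univariateLdsc's
# weighting so jackknife replicates are consistent across the three
# regressions entering rg.
.ldscDelSlopes <- function(stats, scores, M, nBlocks, constrained) {
  d <- .ldscPrep(stats, scores)
  nv <- length(d$chi2)
  N <- mean(d$n)
  y <- if (constrained) d$chi2 - 1 else d$chi2
  block <- ceiling(seq_len(nv) / (nv / nBlocks))
  w <- rep(1, nv)
  fit <- NULL
  for (it in 1:3) {
    fit <- .ldscWls(y, d$ell, w, block, constrained)
    h2hat <- max(min(fit$slope * M / N, 1), 0)
    w <- 1 / pmax(d$ell, 1) / (1 + N * h2hat * d$ell / M)^2
  }
  fit$slopeDel
}

#' Liability-scale conversion factor for observed-scale heritability
#'
#' @param K population lifetime risk (prevalence), in (0, 1).
#' @param P sample case fraction, in (0, 1).
#' @return the multiplicative factor `K^2 (1-K)^2 / (P (1-P) z^2)` with
#'   `z = dnorm(qnorm(1 - K))`.
#' @export
liabilityFactor <- function(K, P) {
  if (K <= 0 || K >= 1) stop("K must lie in (0, 1)")
  if (P <= 0 || P >= 1) stop("P must lie in (0, 1)")
  zK <- dnorm(qnorm(1 - K))
  K^2 * (1 - K)^2 / (P * (1 - P) * zK^2)
}

#' Convert observed-scale heritability to the liability scale
#'
#' @param h2ObsValue observed-scale (0/1) heritability.
#' @inheritParams liabilityFactor
#' @return liability-scale heritability; linear in `h2ObsValue`.
#' @export
observedToLiability <- function(h2ObsValue, K, P) {
  h2ObsValue * liabilityFactor(K, P)
}

#' Permutation null distribution of the heritability estimate
#'
#' For each permutation, case-control labels are permuted by
#' [structuredPermutation()], summary statistics recomputed, and
#' constrained-intercept LD score regression run; the resulting estimates
#' form an empirical null for the heritability.
#'
#' @param cohort a [LiabilityCohort-class].
#' @param scores an [LDScoreTable-class] for the cohort's variants.
#' @param nPerms number of permutations.
#' @param nCubes cubes for the structured permutation.
#' @param seed integer random seed.
#' @param K,P optional liability conversion parameters.
#' @param nBlocks jackknife blocks for each fit.
#' @return numeric vector of h2 estimates (liability scale when K and P are
#'   given, observed scale otherwise); empty when `nPerms = 0`.
#' @export
permutationNullH2 <- function(cohort, scores, nPerms = 20, nCubes = 1000,
                              seed = 1, K = NULL, P = NULL, nBlocks = 50) {
  if (nPerms == 0) return(numeric(0))
  vapply(seq_len(nPerms), function(i) {
    lab <- structuredPermutation(cohort, nCubes = nCubes, seed = seed + i)
    st <- computeSummaryStats(genotypes(cohort), phen = lab,
                              variantTable = variants(cohort))
    fit <- univariateLdsc(st, scores, constrainedIntercept = TRUE,
                          nBlocks = nBlocks, K = K, P = P)
    if (is.na(fit@h2Liab)) fit@h2Obs else fit@h2Liab
  }, numeric(1))
}
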