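#' Score-test association summary statistics
#'
#' Per-variant z from the score test of a regression of phenotype on
#' standardized dosage, after residualizing on optional covariates;
#' `p = 2 * pnorm(-|z|)`.  Monomorphic variants are dropped with a message.
#'
#' @param genotypes dosage matrix (individual x variant) or a
#'   [LiabilityCohort-class].
#' @param phen 0/1 phenotype vector (taken from the cohort when omitted).
#' @param covariates optional numeric covariate matrix.
#' @param variantTable a [VariantTable-class] describing the columns; taken
#'   from the cohort when omitted.
#' @return a [SummaryStats-class]; `beta` holds the standardized-scale
#'   effect estimate `z / sqrt(n)`.
#' @export
computeSummaryStats <- function(genotypes, phen = NULL, covariates = NULL,
                                variantTable = NULL) {
  if (is(genotypes, "LiabilityCohort")) {
    if (is.null(phen)) phen <- phenotype(genotypes)
    if (is.null(variantTable)) variantTable <- variants(genotypes)
    genotypes <- genotypes@genotypes
  }
  y <- as.numeric(phen)
  if (var(y) == 0) stop("phenotype is constant")
  n <- nrow(genotypes)
  keep <- apply(genotypes, 2, function(g) var(g) > 0)
  if (!all(keep))
    message(sum(!keep), " monomorphic variant(s) dropped")
  X <- genotypes[, keep, drop = FALSE]
  C <- cbind(rep(1, n), covariates)
  qrC <- qr(C)
  yr <- qr.resid(qrC, y)
  Xr <- qr.resid(qrC, X)
  sigma <- sqrt(sum(yr^2) / (n - ncol(C)))
  ssx <- sqrt(colSums(Xr^2))
  z <- as.numeric(crossprod(Xr, yr)) / (ssx * sigma)
  vt <- variantTable
  if (is.null(vt))
    vt <- VariantTable(chrom = rep(1L, ncol(genotypes)),
                       pos = seq_len(ncol(genotypes)))
  vtk <- subsetVariants(vt, which(keep))
  SummaryStats(vtk, z = z, n = n, beta = z / sqrt(n))
}

#' Subset a VariantTable by index or id
#'
#' @param vt a [VariantTable-class].
#' @param i integer indices or character ids.
#' @return the subsetted [VariantTable-class].
#' @export
subsetVariants <- function(vt, i) {
  if (is.character(i)) i <- match(i, vt@id)
  new("VariantTable", chrom = vt@chrom[i], pos = vt@pos[i], cm = vt@cm[i],
      id = vt@id[i], a1 = vt@a1[i], a2 = vt@a2[i], maf = vt@maf[i])
}

#' Structure-preserving permutation of case-control labels
#'
#' Principal components 1-3 of the standardized dosage matrix span a space
#' that is subdivided into equal-width cubes; case-control labels are
#' permuted only within cubes, so the global and per-cube case counts are
#' preserved exactly and labels never cross well-separated strata.
#'
#' @param genotypes dosage matrix or [LiabilityCohort-class].
#' @param phen 0/1 labels (from the cohort when omitted).
#' @param nCubes target number of cubes (the grid uses
#'   `ceiling(nCubes^(1/3))` equal-width cells per retained dimension).
#' @param seed integer random seed.
#' @return the permuted label vector, with attribute `"cube"` giving each
#'   individual's cube id.
#' @export
structuredPermutation <- function(genotypes, phen = NULL, nCubes = 1000,
                                  seed = 1) {
  if (is(genotypes, "LiabilityCohort")) {
    if (is.null(phen)) phen <- phenotype(genotypes)
    genotypes <- genotypes@genotypes
  }
  if (nCubes < 1) stop("nCubes must be >= 1")
  set.seed(seed)
  labels <- phen
  keep <- apply(genotypes, 2, var) > 0
  X <- scale(genotypes[, keep, drop = FALSE])
  pc <- prcomp(X, center = FALSE, scale. = FALSE, rank. = 3)
  ok <- pc$sdev[seq_len(min(3, ncol(pc$x)))] > 1e-10
  nd <- sum(ok)
  if (nd < 3)
    warning(sprintf("only %d non-degenerate principal component(s); using a %d-dimensional grid",
                    nd, max(nd, 1)))
  nd <- max(nd, 1)
  kPer <- max(1L, ceiling(nCubes^(1 / 3)))
  cube <- rep(1L, nrow(X))
  for (d in seq_len(nd)) {
    v <- pc$x[, d]
    br <- seq(min(v), max(v), length.out = kPer + 1L)
    br[1] <- br[1] - 1e-9; br[kPer + 1L] <- br[kPer + 1L] + 1e-9
    cell <- findInterval(v, br, rightmost.closed = TRUE)
    cube <- cube + (cell - 1L) * kPer^(d - 1L)
  }
  out <- labels
  for (cb in unique(cube)) {
    idx <- which(cube == cb)
    if (length(idx) > 1L) out[idx] <- labels[sample(idx)]
  }
  attr(out, "cube") <- cube
  out
}

#' Simulate summary statistics directly from the LD score regression model
#'
#' A fast alternative to genotype-level simulation: per-variant z-score
#' pairs are drawn from a bivariate normal with
#' `E[z_t^2] = a_t + N_t * h2obs_t * ell / M` and
#' `E[z1 z2] = sqrt(N1 N2) * rhoGObs * ell / M + nullCorr`, the generative
#' model underlying LD score regression.  `nullCorr` is the sample-overlap
#' term; for cohorts sharing `nShared` controls it equals
#' `nShared * sqrt(P1 P2 / ((1-P1)(1-P2))) / sqrt(N1 N2)`.
#'
#' @param M number of variants.
#' @param h2Obs1,h2Obs2 observed-scale heritabilities of the two traits
#'   (set `h2Obs2 = 0`, `rg = 0` for a single-trait simulation).
#' @param rg genetic correlation; the observed-scale genetic covariance is
#'   `rg * sqrt(h2Obs1 * h2Obs2)`.
#' @param N1,N2 GWAS sample sizes.
#' @param nullCorr sample-overlap correlation of the two traits' z-scores
#'   under the null (0 for disjoint samples).
#' @param intercept1,intercept2 the two univariate intercepts (1 = no
#'   confounding).
#' @param ell per-variant LD scores; drawn as `1 + Gamma(shape 2, scale 5)`
#'   when omitted.
#' @param seed integer random seed.
#' @return a list with `stats1`, `stats2` ([SummaryStats-class]) and
#'   `scores` ([LDScoreTable-class]).
#' @export
simulateSummaryStatsDirect <- function(M, h2Obs1, h2Obs2 = 0, rg = 0,
                                       N1, N2 = N1, nullCorr = 0,
                                       intercept1 = 1, intercept2 = 1,
                                       ell = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(ell)) ell <- 1 + rgamma(M, shape = 2, scale = 5)
  rhoGObs <- rg * sqrt(h2Obs1 * h2Obs2)
  v1 <- intercept1 + N1 * h2Obs1 * ell / M
  v2 <- intercept2 + N2 * h2Obs2 * ell / M
  cv <- sqrt(N1 * N2) * rhoGObs * ell / M + nullCorr
  cv <- pmin(pmax(cv, -sqrt(v1 * v2) + 1e-12), sqrt(v1 * v2) - 1e-12)
  u1 <- rnorm(M); u2 <- rnorm(M)
  z1 <- sqrt(v1) * u1
  z2 <- (cv / sqrt(v1)) * u1 + sqrt(pmax(v2 - cv^2 / v1, 0)) * u2
  vt <- VariantTable(chrom = rep(1L, M), pos = seq_len(M) * 1000L,
                     maf = rep(0.25, M))
  list(stats1 = SummaryStats(vt, z = z1, n = N1),
       stats2 = SummaryStats(vt, z = z2, n = N2),
       scores = new("LDScoreTable", variants = vt, ell = ell,
                    nHaplotypes = NA_integer_))
}

#' Null z-score correlation induced by shared controls
#'
#' @param nShared number of shared control individuals.
#' @param N1,N2 total sample sizes of the two studies.
#' @param P1,P2 sample case fractions.
#' @return the expected correlation of the two traits' null z-scores.
#' @export
sharedControlNullCorr <- function(nShared, N1, N2, P1 = 0.5, P2 = 0.5) {
  nShared * sqrt(P1 * P2 / ((1 - P1) * (1 - P2))) / sqrt(N1 * N2)
}
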