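#' Polygenic scoring configuration
#'
#' Discovery p-value thresholds and the two clumping rounds used for
#' polygenic risk scoring.  Defaults follow the standard two-round scheme:
#' round 1 at 250 kb / r2 0.5, round 2 at 5,000 kb / r2 0.2, with the
#' twelve discovery thresholds 5e-8 ... 0.5, a 1% MAF floor and removal of
#' strand-ambiguous (A/T, G/C) variants.
#'
#' @param pThresholds strictly increasing discovery p-value cutoffs.
#' @param round1,round2 lists with `kb` and `r2` for the two clumping
#'   rounds.
#' @param mafMin minor-allele-frequency floor.
#' @param dropAmbiguous drop A/T and G/C variants.
#' @param pcAlpha significance cutoff for principal-component selection.
#' @return a list of class `PrsConfig`.
#' @export
PrsConfig <- function(pThresholds = c(5e-8, 5e-7, 5e-6, 5e-5, 5e-4, 5e-3,
                                      0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
                      round1 = list(kb = 250, r2 = 0.5),
                      round2 = list(kb = 5000, r2 = 0.2),
                      mafMin = 0.01, dropAmbiguous = TRUE,
                      pcAlpha = 0.0005) {
  if (is.unsorted(pThresholds, strictly = TRUE))
    stop("pThresholds must be strictly increasing")
  if (round1$r2 <= 0 || round1$r2 >= 1 || round2$r2 <= 0 || round2$r2 >= 1)
    stop("r2 cutoffs must lie in (0, 1)")
  structure(list(pThresholds = pThresholds, round1 = round1,
                 round2 = round2, mafMin = mafMin,
                 dropAmbiguous = dropAmbiguous, pcAlpha = pcAlpha),
            class = "PrsConfig")
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly takes the lowest-p unassigned variant as an index and removes
#' all unassigned variants within `distanceKb` whose r2 with the index
#' exceeds `r2Cut`.  Ties in p are broken by (chrom, pos, id) lexicographic
#' order, making the output independent of input row order.
#'
#' @param stats a [SummaryStats-class].
#' @param panel a [HaplotypePanel-class] supplying LD (or a function
#'   `r2fun(idA, idB)` for testing).
#' @param distanceKb physical distance threshold in kb.
#' @param r2Cut LD threshold; neighbours with r2 strictly greater are
#'   removed.
#' @param ids optional subset of variant ids to clump (default: all).
#' @return character vector of retained (index) variant ids.
#' @export
clumpVariants <- function(stats, panel, distanceKb, r2Cut, ids = NULL) {
  vt <- stats@variants
  use <- if (is.null(ids)) seq_len(nVariants(vt)) else match(ids, vt@id)
  if (!length(use)) return(character(0))
  r2fun <- if (is.function(panel)) panel else {
    X <- scale(panel@haplotypes)
    pid <- panel@variants@id
    function(a, b) {
      i <- match(a, pid); j <- match(b, pid)
      as.numeric(cor(X[, i], X[, j, drop = FALSE]))^2
    }
  }
  ord <- use[order(stats@p[use], vt@chrom[use], vt@pos[use], vt@id[use])]
  assigned <- logical(nVariants(vt))
  keep <- character(0)
  for (i in ord) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    keep <- c(keep, vt@id[i])
    nb <- use[!assigned[use] & vt@chrom[use] == vt@chrom[i] &
              abs(vt@pos[use] - vt@pos[i]) <= distanceKb * 1000]
    if (length(nb)) {
      r2 <- vapply(vt@id[nb], function(b) r2fun(vt@id[i], b), numeric(1))
      assigned[nb[r2 > r2Cut]] <- TRUE
    }
  }
  keep
}

#' Two-round LD clumping
#'
#' @inheritParams clumpVariants
#' @param config a [PrsConfig()].
#' @return retained variant ids after both rounds.
#' @export
clumpTwoRounds <- function(stats, panel, config = PrsConfig()) {
  r1 <- clumpVariants(stats, panel, config$round1$kb, config$round1$r2)
  clumpVariants(stats, panel, config$round2$kb, config$round2$r2, ids = r1)
}

#' Per-individual polygenic risk scores
#'
#' `score_i = sum over retained variants with p <= threshold of
#' beta_v * dosage_iv`; missing dosages contribute the variant's mean
#' dosage.  Effect sizes come from the `beta` slot of the summary
#' statistics (log odds ratios), falling back to `z / sqrt(n)`.
#'
#' @param geno dosage matrix with columns named by variant id, or a
#'   [LiabilityCohort-class].
#' @param stats discovery [SummaryStats-class].
#' @param retained variant ids retained by clumping.
#' @param pThreshold discovery p-value cutoff.
#' @return numeric score per individual.
#' @export
prsScore <- function(geno, stats, retained, pThreshold) {
  vtm <- NULL
  if (is(geno, "LiabilityCohort")) {
    vtm <- variants(geno)@id
    geno <- genotypes(geno)
  }
  if (is.null(colnames(geno)) && !is.null(vtm)) colnames(geno) <- vtm
  beta <- effectSizes(stats)
  if (is.null(beta)) beta <- stats@z / sqrt(stats@n)
  sel <- stats@variants@id %in% retained & stats@p <= pThreshold
  ids <- stats@variants@id[sel]
  ids <- ids[ids %in% colnames(geno)]
  if (!length(ids)) {
    warning("no variants pass the threshold; scores are all zero")
    return(rep(0, nrow(geno)))
  }
  b <- beta[match(ids, stats@variants@id)]
  Gm <- geno[, ids, drop = FALSE]
  if (anyNA(Gm)) {
    mu <- colMeans(Gm, na.rm = TRUE)
    for (j in seq_along(ids)) Gm[is.na(Gm[, j]), j] <- mu[j]
  }
  as.numeric(Gm %*% b)
}

#' Select ancestry principal components associated with the phenotype
#'
#' Computes the top principal components of the standardized dosage matrix,
#' regresses the phenotype on all of them jointly (logistic model), and
#' retains those with Wald p below `alpha` (Bonferroni-style fixed cutoff).
#'
#' @param geno dosage matrix or [LiabilityCohort-class].
#' @param phen 0/1 phenotype (from the cohort when omitted).
#' @param nPcs number of components to compute (default 100, limited by
#'   rank).
#' @param alpha per-component significance cutoff (default 0.0005).
#' @return a list with `pcs` (the component matrix), `selected` (indices of
#'   retained components) and `p` (per-component p-values).
#' @export
selectPcs <- function(geno, phen = NULL, nPcs = 100, alpha = 0.0005) {
  if (is(geno, "LiabilityCohort")) {
    if (is.null(phen)) phen <- phenotype(geno)
    geno <- genotypes(geno)
  }
  keep <- apply(geno, 2, var) > 0
  X <- scale(geno[, keep, drop = FALSE])
  k <- min(nPcs, nrow(X) - 1L, ncol(X))
  pc <- prcomp(X, center = FALSE, rank. = k)
  usable <- pc$sdev[seq_len(k)] > 1e-10
  if (sum(usable) < k)
    warning("rank deficiency: only ", sum(usable), " usable components")
  P <- pc$x[, usable, drop = FALSE]
  fit <- glm(phen ~ P, family = binomial())
  sm <- summary(fit)$coefficients
  pv <- rep(NA_real_, ncol(P))
  rows <- match(paste0("P", colnames(P)), rownames(sm))
  pv[!is.na(rows)] <- sm[rows[!is.na(rows)], 4]
  list(pcs = P, selected = which(!is.na(pv) & pv < alpha), p = pv)
}

.nagelkerke <- function(ll0, ll1, n) {
  (1 - exp((2 / n) * (ll0 - ll1))) / (1 - exp((2 / n) * ll0))
}

#' Incremental Nagelkerke R-squared of a polygenic score
#'
#' Fits baseline (covariates-only) and full (covariates + score) logistic
#' models and returns the difference of their Nagelkerke pseudo-R2 values,
#' with the Wald p-value of the score term (likelihood-ratio p behind
#' `lrt = TRUE`).
#'
#' @param phen 0/1 phenotype.
#' @param scores per-individual polygenic scores.
#' @param covariates optional covariate matrix.
#' @param lrt use the likelihood-ratio test instead of Wald.
#' @return a list with `deltaR2`, `p`, `r2Full`, `r2Baseline` and
#'   `converged` (FALSE flags separation; the pseudo-R2 values are then the
#'   boundary values of the fitting path).
#' @export
deltaNagelkerke <- function(phen, scores, covariates = NULL, lrt = FALSE) {
  n <- length(phen)
  if (var(scores) == 0) {
    base <- if (is.null(covariates)) glm(phen ~ 1, family = binomial())
            else glm(phen ~ covariates, family = binomial())
    r2b <- .nagelkerke(as.numeric(logLik(glm(phen ~ 1,
                                             family = binomial()))),
                       as.numeric(logLik(base)), n)
    return(list(deltaR2 = 0, p = NA_real_, r2Full = r2b, r2Baseline = r2b,
                converged = TRUE))
  }
  ll0 <- as.numeric(logLik(glm(phen ~ 1, family = binomial())))
  if (is.null(covariates)) {
    base <- glm(phen ~ 1, family = binomial())
    full <- glm(phen ~ scores, family = binomial())
  } else {
    base <- glm(phen ~ covariates, family = binomial())
    full <- glm(phen ~ covariates + scores, family = binomial())
  }
  llb <- as.numeric(logLik(base)); llf <- as.numeric(logLik(full))
  r2b <- .nagelkerke(ll0, llb, n)
  r2f <- .nagelkerke(ll0, llf, n)
  sm <- summary(full)$coefficients
  p <- if (lrt) pchisq(2 * (llf - llb), df = 1, lower.tail = FALSE)
       else sm["scores", 4]
  list(deltaR2 = r2f - r2b, p = p, r2Full = r2f, r2Baseline = r2b,
       converged = full$converged)
}

#' Decile odds ratios for a polygenic score
#'
#' Scores are cut into ten deciles by rank (ties broken by stable
#' individual order); a logistic model with decile dummies (decile 1 as
#' reference) plus covariates yields per-decile odds ratios with 95%
#' confidence intervals, along with the case:control ratio per decile.
#'
#' @inheritParams deltaNagelkerke
#' @return a data.frame with decile, n, nCases, caseControlRatio, or,
#'   ciLo, ciHi, p (decile 1 has or = 1 by construction).
#' @export
decileOr <- function(phen, scores, covariates = NULL) {
  n <- length(scores)
  if (n < 100) warning("fewer than 10 individuals per decile on average")
  rk <- rank(scores, ties.method = "first")
  dec <- ceiling(rk * 10 / n)
  dec <- pmin(pmax(dec, 1L), 10L)
  if (length(unique(dec)) < 10)
    warning("empty decile(s) after mass ties; deciles merged")
  f <- factor(dec, levels = sort(unique(dec)))
  fit <- if (is.null(covariates)) glm(phen ~ f, family = binomial())
         else glm(phen ~ f + covariates, family = binomial())
  sm <- summary(fit)$coefficients
  lev <- levels(f)
  out <- data.frame(decile = as.integer(lev),
                    n = as.integer(table(f)),
                    nCases = as.integer(tapply(phen, f, sum)))
  out$caseControlRatio <- out$nCases / pmax(out$n - out$nCases, 1)
  out$or <- 1; out$ciLo <- NA_real_; out$ciHi <- NA_real_
  out$p <- NA_real_
  for (k in seq_along(lev)[-1]) {
    rn <- paste0("f", lev[k])
    if (rn %in% rownames(sm)) {
      b <- sm[rn, 1]; se <- sm[rn, 2]
      out$or[k] <- exp(b)
      out$ciLo[k] <- exp(b - 1.96 * se)
      out$ciHi[k] <- exp(b + 1.96 * se)
      out$p[k] <- sm[rn, 4]
    }
  }
  out
}

#' Label-permutation null for the PRS incremental R-squared
#'
#' Case labels are permuted preserving the case count; the incremental
#' Nagelkerke R2 is recomputed for each permutation.
#'
#' @inheritParams deltaNagelkerke
#' @param nPerms number of permutations.
#' @param seed integer random seed.
#' @return a list with `delta` (vector), `mean`, and `q95`.
#' @export
permutationPrs <- function(phen, scores, covariates = NULL, nPerms = 100,
                           seed = 1) {
  set.seed(seed)
  delta <- vapply(seq_len(nPerms), function(i) {
    deltaNagelkerke(sample(phen), scores, covariates)$deltaR2
  }, numeric(1))
  list(delta = delta, mean = mean(delta),
       q95 = as.numeric(quantile(delta, 0.95)))
}

#' Full polygenic risk score analysis across thresholds
#'
#' Filters the discovery statistics (MAF floor, strand-ambiguous removal),
#' clumps in two rounds, scores the target cohort at each threshold, and
#' fits the incremental-R2 model with the supplied covariates.
#'
#' @param stats discovery [SummaryStats-class].
#' @param target target [LiabilityCohort-class] (or dosage matrix with
#'   named columns plus `phen`).
#' @param panel [HaplotypePanel-class] for LD.
#' @param config a [PrsConfig()].
#' @param covariates optional covariate matrix.
#' @param phen phenotype when `target` is a plain matrix.
#' @return a list of class `PrsResult` with the per-threshold table
#'   (`perThreshold`), `bestThreshold`, the best-threshold `scores`, and
#'   the retained variant ids (`retained`).
#' @export
prsAnalysis <- function(stats, target, panel, config = PrsConfig(),
                        covariates = NULL, phen = NULL) {
  if (is(target, "LiabilityCohort")) {
    if (is.null(phen)) phen <- phenotype(target)
  }
  vt <- stats@variants
  keep <- rep(TRUE, nVariants(vt))
  if (!all(is.na(vt@maf))) keep <- keep & (is.na(vt@maf) |
                                           vt@maf >= config$mafMin)
  if (config$dropAmbiguous) {
    amb <- (vt@a1 == "A" & vt@a2 == "T") | (vt@a1 == "T" & vt@a2 == "A") |
           (vt@a1 == "G" & vt@a2 == "C") | (vt@a1 == "C" & vt@a2 == "G")
    keep <- keep & !amb
  }
  fstats <- SummaryStats(subsetVariants(vt, which(keep)),
                         z = stats@z[keep], n = stats@n[keep],
                         p = stats@p[keep],
                         beta = if (!is.null(stats@beta))
                                  stats@beta[keep])
  retained <- clumpTwoRounds(fstats, panel, config)
  rows <- lapply(config$pThresholds, function(pt) {
    sc <- suppressWarnings(prsScore(target, fstats, retained, pt))
    nSnps <- sum(fstats@variants@id %in% retained & fstats@p <= pt)
    d <- deltaNagelkerke(phen, sc, covariates)
    data.frame(pThreshold = pt, nSnps = nSnps, deltaR2 = d$deltaR2,
               p = d$p)
  })
  tab <- do.call(rbind, rows)
  best <- tab$pThreshold[which.max(tab$deltaR2)]
  structure(list(perThreshold = tab, bestThreshold = best,
                 scores = suppressWarnings(
                   prsScore(target, fstats, retained, best)),
                 retained = retained),
            class = "PrsResult")
}
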