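#' Draw bivariate per-variant effect sizes
#'
#' For each causal variant a pair of standardized-genotype effects is drawn
#' from a bivariate normal with per-variant variances `h2Liab_t / Mc` and
#' covariance `rg * sqrt(h2Liab1 * h2Liab2) / Mc`, where
#' `Mc = round(M * propCausal)`.  Non-causal variants get (0, 0), so the
#' per-trait sums of effect variances equal the liability heritabilities in
#' expectation.
#'
#' @param arch a [GeneticArchitecture-class].
#' @param variants a [VariantTable-class] (defines M and the row order).
#' @param seed integer random seed.
#' @return a list with `beta` (M x 2 matrix of standardized-scale effects)
#'   and `causal` (logical vector).
#' @export
drawEffectSizes <- function(arch, variants, seed = 1) {
  validObject(arch)
  set.seed(seed)
  M <- nVariants(variants)
  Mc <- max(1L, round(M * arch@propCausal))
  rho <- arch@rg * sqrt(arch@h2Liab1 * arch@h2Liab2)
  Sigma <- matrix(c(arch@h2Liab1, rho, rho, arch@h2Liab2), 2, 2) / Mc
  ed <- eigen(Sigma, symmetric = TRUE)
  if (any(ed$values < -1e-12))
    stop("effect covariance matrix is not positive semi-definite")
  causal <- rep(FALSE, M)
  causal[sample.int(M, Mc)] <- TRUE
  beta <- matrix(0, M, 2)
  # eigen square root handles the PSD boundary (|rg| = 1) exactly
  L <- ed$vectors %*% (sqrt(pmax(ed$values, 0)) * t(ed$vectors))
  beta[causal, ] <- matrix(rnorm(2 * Mc), Mc, 2) %*% L
  list(beta = beta, causal = causal)
}

# Balding-Nichols stratum frequencies around base frequency p.
.strataFreqs <- function(p, nStrata, fst) {
  if (nStrata == 1L || fst <= 0)
    return(matrix(p, nStrata, length(p), byrow = TRUE))
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  ps <- matrix(rbeta(nStrata * length(p), rep(a, each = nStrata),
                     rep(b, each = nStrata)), nStrata, length(p))
  pmin(pmax(ps, 0.01), 0.99)
}

# Draw a batch of individuals: genotypes by pairing panel haplotypes, with
# optional stratum-specific allele perturbation, plus bivariate genetic
# values and liabilities.
.drawIndividuals <- function(panel, beta, arch, n, strataP = NULL,
                             strata = NULL, mixRate = 0.2) {
  H <- panel@haplotypes
  nh <- nrow(H)
  M <- ncol(H)
  i1 <- sample.int(nh, n, replace = TRUE)
  i2 <- sample.int(nh, n, replace = TRUE)
  G <- H[i1, , drop = FALSE] + H[i2, , drop = FALSE]
  if (!is.null(strataP) && nrow(strataP) > 1L) {
    for (s in unique(strata)) {
      rows <- which(strata == s)
      if (!length(rows)) next
      mix <- matrix(runif(length(rows) * M) < mixRate, length(rows), M)
      fresh <- matrix(rbinom(length(rows) * M, 2L,
                             rep(strataP[s, ], each = length(rows))),
                      length(rows), M)
      Gs <- G[rows, , drop = FALSE]
      Gs[mix] <- fresh[mix]
      G[rows, ] <- Gs
    }
  }
  p <- colMeans(H)
  sdg <- sqrt(2 * p * (1 - p))
  Xc <- sweep(G, 2, 2 * p, "-")
  Xs <- sweep(Xc, 2, sdg, "/")
  gv <- Xs %*% beta                      # n x 2 genetic values
  e1 <- rnorm(n, 0, sqrt(max(0, 1 - arch@h2Liab1)))
  e2 <- rnorm(n, 0, sqrt(max(0, 1 - arch@h2Liab2)))
  list(G = G, gv = gv, lia = cbind(gv[, 1] + e1, gv[, 2] + e2))
}

#' Simulate a liability-threshold case-control cohort
#'
#' Individuals are formed by pairing panel haplotypes (with optional
#' Balding-Nichols stratum perturbation), assigned liability = genetic value
#' + normal environmental residual with total variance 1, and labelled case
#' iff liability exceeds `qnorm(1 - K)`.  Rejection sampling continues in
#' batches until the requested case and control counts are reached or the
#' attempt budget is exhausted.
#'
#' @param panel a [HaplotypePanel-class].
#' @param effects output of [drawEffectSizes()].
#' @param arch a [GeneticArchitecture-class].
#' @param design a [CohortDesign-class]; only the trait's own counts are
#'   used.
#' @param traitIndex 1 or 2.
#' @param seed integer random seed.
#' @param maxAttempts total individuals that may be sampled; default
#'   `500 * nCases / K`.
#' @return a [LiabilityCohort-class] with cases first.
#' @export
simulateLiabilityCohort <- function(panel, effects, arch, design,
                                    traitIndex = 1, seed = 1,
                                    maxAttempts = NULL) {
  validObject(design)
  set.seed(seed)
  K <- if (traitIndex == 1) arch@K1 else arch@K2
  nCase <- if (traitIndex == 1) design@nCases1 else design@nCases2
  nCtrl <- if (traitIndex == 1) design@nControls1 else design@nControls2
  if (is.null(maxAttempts)) maxAttempts <- ceiling(500 * nCase / K)
  thr <- qnorm(1 - K)
  p <- colMeans(panel@haplotypes)
  strataP <- .strataFreqs(p, design@nStrata, design@stratumFst)

  caseG <- list(); caseMeta <- list()
  ctrlG <- list(); ctrlMeta <- list()
  gotCase <- 0L; gotCtrl <- 0L; drawn <- 0L
  batch <- max(500L, min(20000L, ceiling(nCase / max(K, 1e-4) / 10)))
  while ((gotCase < nCase || gotCtrl < nCtrl) && drawn < maxAttempts) {
    nb <- min(batch, maxAttempts - drawn)
    strata <- sample.int(design@nStrata, nb, replace = TRUE)
    d <- .drawIndividuals(panel, effects$beta, arch, nb, strataP, strata)
    drawn <- drawn + nb
    isCase <- d$lia[, traitIndex] > thr
    needCase <- which(isCase)[seq_len(min(sum(isCase), nCase - gotCase))]
    needCtrl <- which(!isCase)[seq_len(min(sum(!isCase), nCtrl - gotCtrl))]
    if (length(needCase)) {
      caseG[[length(caseG) + 1L]] <- d$G[needCase, , drop = FALSE]
      caseMeta[[length(caseMeta) + 1L]] <-
        cbind(strata[needCase], d$lia[needCase, traitIndex],
              d$gv[needCase, traitIndex])
      gotCase <- gotCase + length(needCase)
    }
    if (length(needCtrl)) {
      ctrlG[[length(ctrlG) + 1L]] <- d$G[needCtrl, , drop = FALSE]
      ctrlMeta[[length(ctrlMeta) + 1L]] <-
        cbind(strata[needCtrl], d$lia[needCtrl, traitIndex],
              d$gv[needCtrl, traitIndex])
      gotCtrl <- gotCtrl + length(needCtrl)
    }
  }
  if (gotCase < nCase || gotCtrl < nCtrl)
    stop(sprintf(
      "cohort generation exhausted its attempt budget (%d draws): short %d cases and %d controls",
      drawn, nCase - gotCase, nCtrl - gotCtrl))
  G <- rbind(do.call(rbind, caseG), do.call(rbind, ctrlG))
  meta <- rbind(do.call(rbind, caseMeta), do.call(rbind, ctrlMeta))
  new("LiabilityCohort", genotypes = G,
      phenotype = c(rep(1L, nCase), rep(0L, nCtrl)),
      stratum = as.integer(meta[, 1]), liability = meta[, 2],
      geneticValue = meta[, 3], variants = panel@variants,
      sharedWith = integer(0))
}

#' Simulate two case-control cohorts with literally shared controls
#'
#' Draws both traits' liabilities jointly per individual, ascertains each
#' cohort by its own threshold, and makes `nSharedControls` control rows
#' literally the same individuals in both cohorts (individuals that are
#' controls for both traits).
#'
#' @inheritParams simulateLiabilityCohort
#' @return a list of two [LiabilityCohort-class] objects; `sharedWith` in
#'   cohort 2 gives, for each of its first `nSharedControls` control rows,
#'   the row index of the identical individual in cohort 1.
#' @export
simulateSharedCohorts <- function(panel, effects, arch, design, seed = 1,
                                  maxAttempts = NULL) {
  validObject(design)
  set.seed(seed)
  t1 <- qnorm(1 - arch@K1); t2 <- qnorm(1 - arch@K2)
  nNeed <- c(case1 = design@nCases1, ctrl1 = design@nControls1,
             case2 = design@nCases2, ctrl2 = design@nControls2)
  nShared <- design@nSharedControls
  if (is.null(maxAttempts))
    maxAttempts <- ceiling(500 * max(nNeed[c(1, 3)]) /
                             min(arch@K1, arch@K2))
  p <- colMeans(panel@haplotypes)
  strataP <- .strataFreqs(p, design@nStrata, design@stratumFst)

  pools <- list(case1 = list(), ctrl1 = list(), case2 = list(),
                ctrl2 = list(), shared = list())
  meta <- list(case1 = list(), ctrl1 = list(), case2 = list(),
               ctrl2 = list(), shared = list())
  got <- c(case1 = 0L, ctrl1 = 0L, case2 = 0L, ctrl2 = 0L, shared = 0L)
  nCtrlOwn1 <- design@nControls1 - nShared
  nCtrlOwn2 <- design@nControls2 - nShared
  drawn <- 0L
  batch <- max(500L, min(20000L,
                         ceiling(max(nNeed[c(1, 3)], 1) /
                                   max(min(arch@K1, arch@K2), 1e-4) / 10)))
  take <- function(kind, rows, d, strata, tr) {
    if (!length(rows)) return(invisible())
    pools[[kind]][[length(pools[[kind]]) + 1L]] <<-
      d$G[rows, , drop = FALSE]
    meta[[kind]][[length(meta[[kind]]) + 1L]] <<-
      cbind(strata[rows], d$lia[rows, tr], d$gv[rows, tr])
    got[kind] <<- got[kind] + length(rows)
  }
  while (drawn < maxAttempts &&
         (got["case1"] < nNeed["case1"] || got["ctrl1"] < nCtrlOwn1 ||
          got["case2"] < nNeed["case2"] || got["ctrl2"] < nCtrlOwn2 ||
          got["shared"] < nShared)) {
    nb <- min(batch, maxAttempts - drawn)
    strata <- sample.int(design@nStrata, nb, replace = TRUE)
    d <- .drawIndividuals(panel, effects$beta, arch, nb, strataP, strata)
    drawn <- drawn + nb
    is1 <- d$lia[, 1] > t1; is2 <- d$lia[, 2] > t2
    bothCtrl <- which(!is1 & !is2)
    nTakeShared <- min(length(bothCtrl), nShared - got["shared"])
    sharedRows <- bothCtrl[seq_len(nTakeShared)]
    used <- rep(FALSE, nb); used[sharedRows] <- TRUE
    if (nTakeShared) {
      pools$shared[[length(pools$shared) + 1L]] <-
        d$G[sharedRows, , drop = FALSE]
      meta$shared[[length(meta$shared) + 1L]] <-
        cbind(strata[sharedRows], d$lia[sharedRows, 1], d$gv[sharedRows, 1],
              d$lia[sharedRows, 2], d$gv[sharedRows, 2])
      got["shared"] <- got["shared"] + nTakeShared
    }
    pick <- function(cand, need)
      cand[!used[cand]][seq_len(min(sum(!used[cand]), need))]
    r <- pick(which(is1), nNeed["case1"] - got["case1"])
    take("case1", r, d, strata, 1); used[r] <- TRUE
    r <- pick(which(is2), nNeed["case2"] - got["case2"])
    take("case2", r, d, strata, 2); used[r] <- TRUE
    r <- pick(which(!is1), nCtrlOwn1 - got["ctrl1"])
    take("ctrl1", r, d, strata, 1); used[r] <- TRUE
    r <- pick(which(!is2), nCtrlOwn2 - got["ctrl2"])
    take("ctrl2", r, d, strata, 2); used[r] <- TRUE
  }
  deficit <- c(nNeed["case1"] - got["case1"],
               max(0, nCtrlOwn1 - got["ctrl1"]),
               nNeed["case2"] - got["case2"],
               max(0, nCtrlOwn2 - got["ctrl2"]),
               nShared - got["shared"])
  if (any(deficit > 0))
    stop(sprintf(
      "shared-cohort generation exhausted its budget (%d draws); deficits: cases1=%d controls1=%d cases2=%d controls2=%d shared=%d",
      drawn, deficit[1], deficit[2], deficit[3], deficit[4], deficit[5]))
  bind <- function(x) if (length(x)) do.call(rbind, x) else NULL
  sG <- bind(pools$shared); sM <- bind(meta$shared)
  mk <- function(caseKind, ctrlKind, tr, sharedCols) {
    cG <- bind(pools[[caseKind]]); cM <- bind(meta[[caseKind]])
    oG <- bind(pools[[ctrlKind]]); oM <- bind(meta[[ctrlKind]])
    G <- rbind(cG, sG, oG)
    strat <- c(cM[, 1], if (nShared) sM[, 1], oM[, 1])
    lia <- c(cM[, 2], if (nShared) sM[, sharedCols[1]], oM[, 2])
    gv <- c(cM[, 3], if (nShared) sM[, sharedCols[2]], oM[, 3])
    nCase <- nrow(cG)
    new("LiabilityCohort", genotypes = G,
        phenotype = c(rep(1L, nCase), rep(0L, nrow(G) - nCase)),
        stratum = as.integer(strat), liability = lia, geneticValue = gv,
        variants = panel@variants,
        sharedWith = if (nShared) (nCase + 1L):(nCase + nShared)
                     else integer(0))
  }
  c1 <- mk("case1", "ctrl1", 1, c(2, 3))
  c2 <- mk("case2", "ctrl2", 2, c(4, 5))
  list(cohort1 = c1, cohort2 = c2)
}

#' Replace a fraction of one cohort's cases with cases from another trait
#'
#' Emulates diagnostic misclassification: `round(fraction * nCases)` case
#' rows of cohort B are replaced by genuine trait-A cases drawn from a pool.
#'
#' @param cohortBCases genotype matrix of cohort B's cases.
#' @param cohortACasePool genotype matrix of genuine trait-A cases.
#' @param fraction proportion in \[0, 1\] of B's cases to replace.
#' @param seed integer random seed.
#' @return a list with `genotypes` (the contaminated case matrix) and
#'   `replaced` (the row indices that were swapped).
#' @export
injectMisdiagnosis <- function(cohortBCases, cohortACasePool, fraction,
                               seed = 1) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  set.seed(seed)
  nRep <- round(fraction * nrow(cohortBCases))
  if (nRep > nrow(cohortACasePool))
    stop(sprintf("misdiagnosis pool too small: need %d, have %d",
                 nRep, nrow(cohortACasePool)))
  out <- cohortBCases
  if (nRep > 0) {
    rows <- sample.int(nrow(cohortBCases), nRep)
    src <- sample.int(nrow(cohortACasePool), nRep)
    out[rows, ] <- cohortACasePool[src, , drop = FALSE]
  } else rows <- integer(0)
  list(genotypes = out, replaced = sort(rows))
}
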