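# Shared fixture builders; everything is generated in code.

tinyPanel <- function(seed = 3, nHap = 60, nVar = 120, bsm = 10) {
  simulateReferencePanel(nHap, nVar, blockSizeMean = bsm, seed = seed)
}

# Hand-built panel: variant positions and haplotype columns under full
# control (for exact LD-score examples).  `dup` duplicates column pairs.
manualPanel <- function(pos, H, blockSizes = NULL) {
  nVar <- ncol(H)
  if (is.null(blockSizes)) blockSizes <- rep(1L, nVar)
  ends <- cumsum(blockSizes)
  vt <- VariantTable(chrom = rep(1L, nVar), pos = as.integer(pos),
                     maf = pmin(colMeans(H), 1 - colMeans(H)))
  new("HaplotypePanel", variants = vt, haplotypes = H,
      blockBounds = cbind(c(0L, head(ends, -1)), ends))
}

# Balanced two-stratum genotype matrix with strongly diverged frequencies;
# returns genotypes, stratum labels and a stratum-confounded phenotype.
twoStrataCohort <- function(n = 200, m = 80, seed = 5, caseFrac = c(0.8, 0.2)) {
  set.seed(seed)
  stratum <- rep(1:2, each = n / 2)
  p <- cbind(runif(m, 0.05, 0.3), runif(m, 0.7, 0.95))
  G <- t(vapply(stratum, function(s) rbinom(m, 2L, p[, s]), numeric(m)))
  phen <- unlist(lapply(1:2, function(s)
    rbinom(n / 2, 1L, caseFrac[s])))
  list(genotypes = G, stratum = stratum, phenotype = as.integer(phen))
}

# Independent-variant case/control genotypes for the heterogeneity test:
# controls at frequency p, a `contamFrac` subgroup of cases carries the
# risk alleles at p + delta, remaining cases at p (null) or everyone at a
# uniformly diluted frequency (pleiotropy = TRUE).
buhmboxCohort <- function(nCase = 300, nCtrl = 300, m = 100, p = 0.3,
                          delta = 0.1, contamFrac = 0, pleiotropy = FALSE,
                          seed = 1) {
  set.seed(seed)
  pv <- rep(p, m)
  drawRows <- function(n, pr) t(vapply(seq_len(n),
                                       function(i) rbinom(m, 2L, pr),
                                       numeric(m)))
  ctrl <- drawRows(nCtrl, pv)
  if (pleiotropy) {
    cases <- drawRows(nCase, pv + delta * contamFrac)
  } else {
    nContam <- round(contamFrac * nCase)
    cases <- rbind(drawRows(nContam, pv + delta),
                   drawRows(nCase - nContam, pv))
  }
  rs <- RiskAlleleSet(sprintf("rs%03d", seq_len(m)),
                      pControl = pv, pCase = pv + delta)
  list(cases = cases, controls = ctrl, riskSet = rs)
}
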