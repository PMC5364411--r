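mkStats <- function(p, pos = seq_along(p) * 1000L, chrom = rep(1L, length(p)),
                    beta = NULL) {
  vt <- VariantTable(chrom = chrom, pos = pos)
  z <- qnorm(p / 2, lower.tail = FALSE)
  SummaryStats(vt, z = z, n = 1000, p = 2 * pnorm(-abs(z)), beta = beta)
}

test_that("clumping keeps only the most significant of redundant variants", {
  st <- mkStats(c(1e-8, 1e-4, 1e-2), pos = c(1000L, 2000L, 3000L))
  allLd <- function(a, b) 1
  expect_identical(clumpVariants(st, allLd, 250, 0.5), "snp1")
  noLd <- function(a, b) 0
  expect_setequal(clumpVariants(st, noLd, 250, 0.5),
                  c("snp1", "snp2", "snp3"))
})

test_that("clumping equals an exhaustive greedy oracle on a toy LD matrix", {
  set.seed(9)
  m <- 20
  R2 <- matrix(runif(m * m), m, m); R2 <- (R2 + t(R2)) / 2; diag(R2) <- 1
  p <- runif(m)
  pos <- seq_len(m) * 10000L
  st <- mkStats(p, pos = pos)
  ids <- st@variants@id
  r2fun <- function(a, b) R2[match(a, ids), match(b, ids)]
  got <- clumpVariants(st, r2fun, distanceKb = 100, r2Cut = 0.6)
  # independent oracle: explicit loop over significance order
  alive <- rep(TRUE, m)
  keep <- character(0)
  for (i in order(p)) {
    if (!alive[i]) next
    keep <- c(keep, ids[i])
    near <- abs(pos - pos[i]) <= 100 * 1000 & alive
    near[i] <- FALSE
    alive[near & R2[i, ] > 0.6] <- FALSE
    alive[i] <- FALSE
  }
  expect_identical(got, keep)
})

test_that("tied p-values clump deterministically by position", {
  # the container enforces position order, so ties resolve reproducibly
  expect_error(VariantTable(chrom = c(1L, 1L), pos = c(5L, 3L)),
               "strictly increasing")
  st <- mkStats(rep(1e-4, 3), pos = c(1000L, 3000L, 5000L))
  got <- clumpVariants(st, function(a, b) 1, 250, 0.5)
  expect_identical(got, "snp1")
})

test_that("scores follow the closed-form weighted allele count", {
  st <- mkStats(c(1e-8), pos = 1000L, beta = log(2))
  G <- matrix(c(0, 1, 2), 3, 1, dimnames = list(NULL, "snp1"))
  sc <- prsScore(G, st, retained = "snp1", pThreshold = 0.05)
  expect_equal(sc, c(0, log(2), 2 * log(2)))
  # zero effects give zero scores
  st0 <- mkStats(c(1e-8), pos = 1000L, beta = 0)
  expect_equal(prsScore(G, st0, "snp1", 0.05), c(0, 0, 0))
  # missing dosages are mean-imputed
  Gna <- G; Gna[2, 1] <- NA
  scNa <- prsScore(Gna, st, "snp1", 0.05)
  expect_equal(scNa[2], log(2) * mean(c(0, 2)))
})

test_that("an allele flip shifts scores by a constant", {
  set.seed(10)
  st <- mkStats(rep(1e-6, 3), pos = c(1000L, 2000L, 3000L),
                beta = c(0.5, -0.2, 0.3))
  G <- matrix(rbinom(15, 2, 0.5), 5, 3,
              dimnames = list(NULL, st@variants@id))
  sc <- prsScore(G, st, st@variants@id, 0.05)
  # flip variant 2's coding: dosage 2-d with effect -beta
  G2 <- G; G2[, 2] <- 2 - G2[, 2]
  st2 <- mkStats(rep(1e-6, 3), pos = c(1000L, 2000L, 3000L),
                 beta = c(0.5, 0.2, 0.3))
  sc2 <- prsScore(G2, st2, st@variants@id, 0.05)
  expect_equal(sc2 - sc, rep(2 * 0.2, 5))
})

test_that("principal-component selection flags structure confounding", {
  tc <- twoStrataCohort(n = 200, m = 80, seed = 12)
  sel <- selectPcs(tc$genotypes, tc$phenotype, nPcs = 20)
  expect_true(1 %in% sel$selected)
  selAll <- selectPcs(tc$genotypes, tc$phenotype, nPcs = 20, alpha = 1)
  expect_identical(selAll$selected, seq_len(ncol(selAll$pcs)))
  # unconfounded phenotype: usually nothing is retained at alpha = 5e-4
  set.seed(13)
  selNull <- selectPcs(tc$genotypes, rbinom(200, 1L, 0.5), nPcs = 20)
  expect_lte(length(selNull$selected), 1)
})

test_that("incremental Nagelkerke R2 handles degenerate and perfect scores", {
  set.seed(14)
  y <- rbinom(200, 1L, 0.5)
  d0 <- deltaNagelkerke(y, rep(0, 200))
  expect_identical(d0$deltaR2, 0)
  expect_true(is.na(d0$p))
  dPerf <- suppressWarnings(deltaNagelkerke(y, as.numeric(y)))
  expect_gt(dPerf$deltaR2, 0.9)
})

test_that("incremental R2 matches an independent Newton-solver oracle", {
  set.seed(15)
  n <- 40
  sex <- rbinom(n, 1L, 0.5)
  score <- round(rnorm(n), 3)
  y <- rbinom(n, 1L, plogis(-0.2 + 0.9 * score + 0.3 * sex))
  got <- deltaNagelkerke(y, score, covariates = cbind(sex))
  newtonLl <- function(X) {
    b <- rep(0, ncol(X))
    for (it in 1:60) {
      mu <- plogis(X %*% b)
      W <- as.numeric(mu * (1 - mu))
      b <- b + solve(t(X) %*% (X * W), t(X) %*% (y - mu))
    }
    mu <- plogis(X %*% b)
    sum(y * log(mu) + (1 - y) * log(1 - mu))
  }
  ll0 <- newtonLl(matrix(1, n, 1))
  llb <- newtonLl(cbind(1, sex))
  llf <- newtonLl(cbind(1, sex, score))
  nag <- function(l1) (1 - exp((2 / n) * (ll0 - l1))) /
                      (1 - exp((2 / n) * ll0))
  expect_equal(got$deltaR2, nag(llf) - nag(llb), tolerance = 1e-6)
})

test_that("incremental R2 is invariant to affine rescaling of the score", {
  set.seed(16)
  y <- rbinom(300, 1L, 0.5)
  sc <- rnorm(300) + 0.5 * y
  d1 <- deltaNagelkerke(y, sc)
  d2 <- deltaNagelkerke(y, 3 * sc - 7)
  expect_equal(d1$deltaR2, d2$deltaR2, tolerance = 1e-8)
  expect_equal(d1$p, d2$p, tolerance = 1e-8)
})

test_that("decile odds ratios use decile 1 as reference and rank with score", {
  set.seed(17)
  n <- 800
  sc <- rnorm(n)
  y <- rbinom(n, 1L, plogis(-0.5 + 0.9 * sc))
  tab <- decileOr(y, sc)
  expect_identical(nrow(tab), 10L)
  expect_identical(tab$or[1], 1)
  expect_true(all(abs(tab$n - 80) <= 1))
  expect_gt(cor(tab$decile, tab$or, method = "spearman"), 0.5)
  # null scores: confidence intervals mostly cover 1
  y0 <- rbinom(n, 1L, 0.5)
  tab0 <- decileOr(y0, rnorm(n))
  covered <- sum(tab0$ciLo[-1] <= 1 & tab0$ciHi[-1] >= 1)
  expect_gte(covered, 8)
})

test_that("label permutation nulls out a predictive score", {
  set.seed(18)
  n <- 400
  sc <- rnorm(n)
  y <- rbinom(n, 1L, plogis(-0.3 + 1.2 * sc))
  dObs <- deltaNagelkerke(y, sc)$deltaR2
  perm <- permutationPrs(y, sc, nPerms = 30, seed = 4)
  expect_lt(perm$mean, dObs)
  expect_lt(perm$mean, 0.02)
  # reproducibility
  perm2 <- permutationPrs(y, sc, nPerms = 30, seed = 4)
  expect_identical(perm$delta, perm2$delta)
})

test_that("the threshold sweep runs end-to-end on a synthetic cohort", {
  panel <- tinyPanel(nVar = 200, nHap = 100, bsm = 10)
  arch <- GeneticArchitecture(h2Liab1 = 0.4, h2Liab2 = 0.4, rg = 0.9,
                              K1 = 0.3, K2 = 0.3, propCausal = 0.3)
  eff <- drawEffectSizes(arch, variants(panel), seed = 2)
  des <- CohortDesign(nCases1 = 200, nControls1 = 200, nCases2 = 200,
                      nControls2 = 200)
  cc <- simulateSharedCohorts(panel, eff, arch, des, seed = 3)
  disc <- computeSummaryStats(cc$cohort2)
  res <- prsAnalysis(disc, cc$cohort1, panel)
  expect_s3_class(res$perThreshold, "data.frame")
  expect_identical(nrow(res$perThreshold), 12L)
  expect_true(res$bestThreshold %in% res$perThreshold$pThreshold)
  expect_true(all(res$perThreshold$deltaR2 >= -1e-9, na.rm = TRUE))
})
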