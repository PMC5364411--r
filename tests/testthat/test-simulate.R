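test_that("reference panel is deterministic and block-structured", {
  p1 <- simulateReferencePanel(200, 1000, blockSizeMean = 50, seed = 1)
  p2 <- simulateReferencePanel(200, 1000, blockSizeMean = 50, seed = 1)
  expect_identical(haplotypes(p1), haplotypes(p2))
  expect_identical(blockBounds(p1), blockBounds(p2))
  nb <- nrow(blockBounds(p1))
  expect_gt(nb, 12)
  expect_lt(nb, 30)
  bb <- blockBounds(p1)
  expect_identical(unname(bb[1, 1]), 0L)
  expect_identical(unname(bb[nb, 2]), 1000L)
  f <- colMeans(haplotypes(p1))
  expect_true(all(f >= 0.005 & f <= 0.995))
})

test_that("within-block LD decays with distance; blocks are independent", {
  p <- simulateReferencePanel(200, 1000, blockSizeMean = 50, seed = 1)
  bb <- blockBounds(p)
  H <- haplotypes(p)
  adjacent <- c(); distant <- c(); cross <- c()
  for (b in seq_len(nrow(bb))) {
    idx <- (bb[b, 1] + 1L):bb[b, 2]
    if (length(idx) >= 4) {
      adjacent <- c(adjacent, cor(H[, idx[1]], H[, idx[2]])^2)
      distant <- c(distant,
                   cor(H[, idx[1]], H[, idx[length(idx)]])^2)
    }
    if (b > 1)
      cross <- c(cross, cor(H[, bb[b - 1, 2]], H[, bb[b, 1] + 1L])^2)
  }
  expect_gt(mean(adjacent), mean(distant))
  # independent blocks: cross-block r2 is sampling noise around 1/(n-1)
  expect_lt(mean(cross), 3 / (nrow(H) - 1))
})

test_that("effect-size draws match the requested bivariate architecture", {
  vt <- VariantTable(chrom = rep(1L, 10000), pos = seq_len(10000) * 100L,
                     maf = rep(0.3, 10000))
  # independence at rg = 0
  e0 <- drawEffectSizes(GeneticArchitecture(rg = 0, propCausal = 0.5),
                        vt, seed = 2)
  r0 <- cor(e0$beta[e0$causal, 1], e0$beta[e0$causal, 2])
  expect_lt(abs(r0), 3 / sqrt(sum(e0$causal)))
  # perfect correlation with equal scales
  e1 <- drawEffectSizes(GeneticArchitecture(h2Liab1 = 0.1, h2Liab2 = 0.1,
                                            rg = 1, propCausal = 0.5),
                        vt, seed = 3)
  expect_equal(e1$beta[, 1], e1$beta[, 2], tolerance = 1e-10)
  # the default cross-trait architecture: empirical correlation near 0.143
  e <- drawEffectSizes(GeneticArchitecture(propCausal = 0.5), vt, seed = 4)
  expect_equal(sum(e$causal), 5000)
  rEmp <- cor(e$beta[e$causal, 1], e$beta[e$causal, 2])
  expect_lt(abs(rEmp - 0.143), 3 / sqrt(5000))
  # per-trait variance sums recover the liability heritabilities
  expect_equal(sum(e$beta[, 1]^2), 0.082, tolerance = 0.05 * 3)
  expect_equal(sum(e$beta[, 2]^2), 0.23, tolerance = 0.1 * 3)
})

test_that("liability cohorts respect the threshold model", {
  panel <- tinyPanel()
  arch <- GeneticArchitecture(h2Liab1 = 0, h2Liab2 = 0, rg = 0,
                              K1 = 0.5, K2 = 0.5)
  eff <- drawEffectSizes(arch, variants(panel), seed = 1)
  des <- CohortDesign(nCases1 = 200, nControls1 = 200)
  coh <- simulateLiabilityCohort(panel, eff, arch, des, seed = 9)
  expect_identical(sum(phenotype(coh)), 200L)
  # h2 = 0: no genetic case-control difference
  gvCase <- coh@geneticValue[phenotype(coh) == 1L]
  gvCtrl <- coh@geneticValue[phenotype(coh) == 0L]
  expect_lt(abs(mean(gvCase) - mean(gvCtrl)), 1e-6)
  expect_true(all(coh@liability[phenotype(coh) == 1L] > 0))
  expect_true(all(coh@liability[phenotype(coh) == 0L] <= 0))
})

test_that("case yield follows the binomial sampling oracle", {
  # K = 0.1 over a budget of 20,000 draws: expected 2,000 cases, SD ~42.
  # Requesting E - 3*SD must succeed; requesting E + 3*SD must fail.
  panel <- tinyPanel()
  arch <- GeneticArchitecture(h2Liab1 = 0.1, h2Liab2 = 0.1, rg = 0,
                              K1 = 0.1, K2 = 0.1)
  eff <- drawEffectSizes(arch, variants(panel), seed = 1)
  sdN <- sqrt(20000 * 0.1 * 0.9)
  desOk <- CohortDesign(nCases1 = floor(2000 - 3 * sdN), nControls1 = 100)
  expect_s4_class(
    simulateLiabilityCohort(panel, eff, arch, desOk, seed = 11,
                            maxAttempts = 20000),
    "LiabilityCohort")
  desBad <- CohortDesign(nCases1 = ceiling(2000 + 3 * sdN),
                         nControls1 = 100)
  expect_error(
    simulateLiabilityCohort(panel, eff, arch, desBad, seed = 11,
                            maxAttempts = 20000),
    "short")
})

test_that("realized genetic variance matches the generating heritability", {
  panel <- tinyPanel(nVar = 200, nHap = 120)
  arch <- GeneticArchitecture(h2Liab1 = 0.3, h2Liab2 = 0.3, rg = 0,
                              K1 = 0.5, K2 = 0.5, propCausal = 0.5)
  stats <- vapply(1:4, function(s) {
    eff <- drawEffectSizes(arch, variants(panel), seed = s)
    coh <- simulateLiabilityCohort(
      panel, eff, arch, CohortDesign(nCases1 = 500, nControls1 = 500),
      seed = s)
    c(var(coh@geneticValue), var(coh@liability))
  }, numeric(2))
  # LD makes the realized genic variance noisy around h2 across draws
  expect_equal(mean(stats[1, ]), 0.3, tolerance = 0.35)
  # environmental residual brings total liability variance to ~1
  expect_equal(mean(stats[2, ]), 1, tolerance = 0.15)
})

test_that("shared controls are literally identical rows in both cohorts", {
  panel <- tinyPanel()
  arch <- GeneticArchitecture(h2Liab1 = 0.1, h2Liab2 = 0.1, rg = 0,
                              K1 = 0.3, K2 = 0.3)
  eff <- drawEffectSizes(arch, variants(panel), seed = 1)
  des <- CohortDesign(nCases1 = 100, nControls1 = 120, nCases2 = 100,
                      nControls2 = 120, nSharedControls = 60)
  cc <- simulateSharedCohorts(panel, eff, arch, des, seed = 21)
  s1 <- cc$cohort1@sharedWith
  s2 <- cc$cohort2@sharedWith
  expect_length(s1, 60)
  expect_identical(genotypes(cc$cohort1)[s1, ],
                   genotypes(cc$cohort2)[s2, ])
  expect_identical(sum(phenotype(cc$cohort1)), 100L)
  expect_identical(sum(phenotype(cc$cohort2) == 0L), 120L)
})

test_that("shared controls induce the predicted null z-score correlation", {
  panel <- tinyPanel(nVar = 800, nHap = 120, bsm = 8)
  arch <- GeneticArchitecture(h2Liab1 = 0, h2Liab2 = 0, rg = 0,
                              K1 = 0.5, K2 = 0.5)
  eff <- drawEffectSizes(arch, variants(panel), seed = 1)
  des <- CohortDesign(nCases1 = 300, nControls1 = 300, nCases2 = 300,
                      nControls2 = 300, nSharedControls = 150)
  cc <- simulateSharedCohorts(panel, eff, arch, des, seed = 31)
  z1 <- zScores(computeSummaryStats(cc$cohort1))
  z2 <- zScores(computeSummaryStats(cc$cohort2))
  expected <- sharedControlNullCorr(150, 600, 600, 0.5, 0.5)  # 0.25
  expect_equal(cor(z1, z2), expected, tolerance = 0.4)
  expect_gt(cor(z1, z2), 0.1)
})

test_that("misdiagnosis injection swaps exactly the requested rows", {
  cases <- matrix(0L, 200, 10)
  pool <- matrix(1L, 300, 10)
  none <- injectMisdiagnosis(cases, pool, 0, seed = 1)
  expect_identical(none$genotypes, cases)
  expect_length(none$replaced, 0)
  some <- injectMisdiagnosis(cases, pool, 0.05, seed = 1)
  expect_length(some$replaced, 10)
  expect_true(all(some$genotypes[some$replaced, ] == 1L))
  expect_true(all(some$genotypes[-some$replaced, ] == 0L))
  all_ <- injectMisdiagnosis(cases, pool, 1, seed = 1)
  expect_true(all(all_$genotypes == 1L))
  expect_error(injectMisdiagnosis(cases, pool[1:5, ], 0.5, seed = 1),
               "pool too small")
})
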