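test_that("a pure null yields heritability estimates around zero", {
  hits <- vapply(1:20, function(s) {
    sim <- simulateSummaryStatsDirect(M = 20000, h2Obs1 = 0, N1 = 30000,
                                      seed = s)
    fit <- univariateLdsc(sim$stats1, sim$scores, M = 20000,
                          constrainedIntercept = TRUE, nBlocks = 100)
    abs(h2Obs(fit)) < 2 * fit@seH2
  }, logical(1))
  expect_gte(sum(hits), 17)
})

test_that("confounding inflates the free intercept and deflates h2", {
  sim <- simulateSummaryStatsDirect(M = 30000, h2Obs1 = 0.2, N1 = 30000,
                                    intercept1 = 1.3, seed = 4)
  free <- univariateLdsc(sim$stats1, sim$scores, M = 30000,
                         constrainedIntercept = FALSE, nBlocks = 100)
  cons <- univariateLdsc(sim$stats1, sim$scores, M = 30000,
                         constrainedIntercept = TRUE, nBlocks = 100)
  expect_gt(free@intercept, 1)
  expect_identical(cons@intercept, 1)
  # the constrained fit absorbs the inflation into the slope
  expect_lt(h2Obs(free), h2Obs(cons))
  expect_equal(h2Obs(free), 0.2, tolerance = 0.05)
})

test_that("liability conversion matches its closed form", {
  expect_equal(observedToLiability(0, 0.1, 0.4), 0)
  expect_equal(liabilityFactor(0.5, 0.5), pi / 2, tolerance = 1e-12)
  expect_equal(observedToLiability(0.2, 0.01, 0.3),
               2 * observedToLiability(0.1, 0.01, 0.3))
  expect_error(liabilityFactor(0, 0.5), "K must")
  expect_error(liabilityFactor(0.5, 1), "P must")
})

test_that("self-correlation recovers rg = 1 with matching intercepts", {
  sim <- simulateSummaryStatsDirect(M = 30000, h2Obs1 = 0.2, N1 = 30000,
                                    seed = 5)
  biv <- bivariateLdsc(sim$stats1, sim$stats1, sim$scores, M = 30000,
                       nBlocks = 100)
  expect_equal(rgEstimate(biv), 1, tolerance = 0.02)
  expect_equal(biv@crossIntercept, biv@fit1@intercept, tolerance = 0.02)
})

test_that("independent traits give a null genetic correlation", {
  hits <- vapply(1:12, function(s) {
    sim <- simulateSummaryStatsDirect(M = 20000, h2Obs1 = 0.2,
                                      h2Obs2 = 0.3, rg = 0, N1 = 30000,
                                      N2 = 30000, seed = 100 + s)
    biv <- bivariateLdsc(sim$stats1, sim$stats2, sim$scores, M = 20000,
                         nBlocks = 100)
    abs(rgEstimate(biv)) < 2 * biv@seRg
  }, logical(1))
  expect_gte(sum(hits), 10)
})

test_that("jackknife SEs track the empirical spread of the estimator", {
  res <- vapply(1:30, function(s) {
    sim <- simulateSummaryStatsDirect(M = 10000, h2Obs1 = 0.2, N1 = 20000,
                                      seed = 200 + s)
    fit <- univariateLdsc(sim$stats1, sim$scores, M = 10000,
                          constrainedIntercept = TRUE, nBlocks = 100)
    c(h2Obs(fit), fit@seH2)
  }, numeric(2))
  ratio <- sd(res[1, ]) / mean(res[2, ])
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
  # and the estimator is unbiased under the generating model
  expect_lt(abs(mean(res[1, ]) - 0.2), 3 * sd(res[1, ]) / sqrt(30))
})

test_that("allele flips between tables are corrected in bivariate mode", {
  sim <- simulateSummaryStatsDirect(M = 20000, h2Obs1 = 0.2, N1 = 30000,
                                    seed = 6)
  st <- sim$stats1
  vtFlip <- st@variants
  a1 <- vtFlip@a1; vtFlip@a1 <- vtFlip@a2; vtFlip@a2 <- a1
  stFlip <- SummaryStats(vtFlip, z = -st@z, n = st@n)
  biv <- bivariateLdsc(st, stFlip, sim$scores, M = 20000, nBlocks = 100)
  expect_equal(rgEstimate(biv), 1, tolerance = 0.02)
})

test_that("permutation-null machinery composes and returns estimates", {
  panel <- tinyPanel(nVar = 300, nHap = 100, bsm = 10)
  arch <- GeneticArchitecture(h2Liab1 = 0.2, h2Liab2 = 0.2, rg = 0,
                              K1 = 0.3, K2 = 0.3)
  eff <- drawEffectSizes(arch, variants(panel), seed = 1)
  coh <- simulateLiabilityCohort(
    panel, eff, arch, CohortDesign(nCases1 = 150, nControls1 = 150),
    seed = 2)
  scores <- computeLDScores(panel, windowCm = 0.05)
  expect_length(permutationNullH2(coh, scores, nPerms = 0), 0)
  h2p <- permutationNullH2(coh, scores, nPerms = 2, nCubes = 27, seed = 5,
                           nBlocks = 20)
  expect_length(h2p, 2)
  expect_true(all(is.finite(h2p)))
})
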