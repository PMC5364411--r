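mkFit <- function(slope, intercept = 1) {
  new("LdscFit", slope = slope, intercept = intercept, h2Obs = NA_real_,
      h2Liab = NA_real_, seH2 = NA_real_, meanChi2 = NA_real_,
      nBlocks = 1L, constrained = intercept == 1, M = 1, nMean = 1)
}

test_that("residualization with slope 0 is a no-op", {
  sim <- simulateSummaryStatsDirect(M = 1000, h2Obs1 = 0.2, N1 = 5000,
                                    seed = 1)
  out <- residualizeOnLdscore(sim$stats1, sim$scores, mkFit(0))
  expect_equal(pValues(out), pValues(sim$stats1), tolerance = 1e-12)
  expect_equal(zScores(out), zScores(sim$stats1), tolerance = 1e-12)
})

test_that("identical LD scores shift chi-squares uniformly, keeping ranks", {
  sim <- simulateSummaryStatsDirect(M = 1000, h2Obs1 = 0.2, N1 = 5000,
                                    ell = rep(5, 1000), seed = 2)
  out <- residualizeOnLdscore(sim$stats1, sim$scores, mkFit(0.05))
  big <- zScores(sim$stats1)^2 > 0.05 * 5 + 1e-6  # unfloored entries
  expect_identical(order(pValues(out)[big]),
                   order(pValues(sim$stats1)[big]))
  shift <- zScores(sim$stats1)^2 - zScores(out)^2
  expect_equal(max(shift[big]) - min(shift[big]), 0, tolerance = 1e-9)
})

test_that("residualized statistics barely regress on LD score", {
  # weak-signal regime (mean chi2 ~ 1.1): the flooring of negative
  # residual chi-squares then distorts the fit only slightly
  sim <- simulateSummaryStatsDirect(M = 20000, h2Obs1 = 0.01, N1 = 20000,
                                    seed = 3)
  fit <- univariateLdsc(sim$stats1, sim$scores, M = 20000, nBlocks = 100)
  out <- residualizeOnLdscore(sim$stats1, sim$scores, fit)
  refit <- univariateLdsc(out, sim$scores, M = 20000, nBlocks = 100)
  expect_lt(abs(refit@slope), 0.3 * abs(fit@slope))
  expect_equal(mean(zScores(out)^2) - 1, fit@intercept - 1,
               tolerance = 0.05)
})

test_that("variants missing an LD score are dropped with a count", {
  sim <- simulateSummaryStatsDirect(M = 500, h2Obs1 = 0.2, N1 = 5000,
                                    seed = 4)
  sub <- new("LDScoreTable",
             variants = subsetVariants(variants(sim$scores), 1:400),
             ell = ldScores(sim$scores)[1:400], nHaplotypes = NA_integer_)
  expect_message(out <- residualizeOnLdscore(sim$stats1, sub, mkFit(0.01)),
                 "100 variant")
  expect_identical(nVariants(out), 400L)
})

test_that("cFDR reduces to the unconditional estimator when uninformative", {
  set.seed(5)
  p1 <- runif(50)
  p2 <- rep(1, 50)
  cf <- conditionalFdr(p1, p2)
  uncond <- pmin(pmax(p1 * 50 / rank(p1, ties.method = "max"), p1), 1)
  expect_equal(cf, uncond, tolerance = 1e-12)
})

test_that("the doubly-smallest variant keeps its raw p-value", {
  p1 <- c(1e-6, 0.2, 0.4, 0.6, 0.8, 0.9, 0.3, 0.5, 0.7, 0.95)
  p2 <- c(1e-5, 0.3, 0.2, 0.9, 0.5, 0.6, 0.4, 0.8, 0.7, 0.99)
  cf <- conditionalFdr(p1, p2)
  expect_equal(cf[1], 1e-6)
})

test_that("cFDR matches an exhaustive double-loop oracle on a 12-row table", {
  p1 <- c(0.001, 0.20, 0.04, 0.55, 0.02, 0.80, 0.10, 0.30, 0.04, 0.95,
          0.62, 0.007)
  p2 <- c(0.010, 0.15, 0.15, 0.70, 0.03, 0.90, 0.05, 0.44, 0.02, 0.60,
          0.33, 0.500)
  got <- conditionalFdr(p1, p2)
  oracle <- vapply(seq_along(p1), function(i) {
    num <- sum(p2 <= p2[i])
    den <- sum(p1 <= p1[i] & p2 <= p2[i])
    min(max(p1[i] * num / den, p1[i]), 1)
  }, numeric(1))
  expect_identical(got, oracle)
})

test_that("cFDR handles large vectors with ties against the oracle", {
  set.seed(6)
  M <- 1500
  p1 <- pmin(round(runif(M)^2, 3) + 1e-4, 1)
  p2 <- pmin(round(runif(M)^2, 3) + 1e-4, 1)
  got <- conditionalFdr(p1, p2)
  oracle <- vapply(seq_len(M), function(i) {
    num <- sum(p2 <= p2[i])
    den <- sum(p1 <= p1[i] & p2 <= p2[i])
    min(max(p1[i] * num / den, p1[i]), 1)
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-14)
})

test_that("shared-control adjustment decorrelates null z-scores", {
  expect_equal(sharedControlAdjust(c(1, -2), c(0.5, 0.3), 0),
               c(0.5, 0.3))
  z <- c(1.3, -0.4, 2.2)
  adj <- sharedControlAdjust(z, z, 1 - 1e-9)
  expect_equal(adj, rep(0, 3), tolerance = 1e-3)
  expect_error(sharedControlAdjust(1, 1, 1), "nullCorr")
  sim <- simulateSummaryStatsDirect(M = 20000, h2Obs1 = 0, h2Obs2 = 0,
                                    rg = 0, N1 = 1e4, N2 = 1e4,
                                    nullCorr = 0.3, seed = 7)
  zAdj <- sharedControlAdjust(zScores(sim$stats1), zScores(sim$stats2),
                              0.3)
  expect_lt(abs(cor(zScores(sim$stats1), zAdj)), 3 / sqrt(20000))
})

test_that("locus clumping groups correlated sub-threshold variants", {
  set.seed(8)
  H <- matrix(rbinom(200 * 4, 1L, 0.5), 200, 4)
  H[, 2] <- H[, 1]
  panel <- manualPanel(pos = c(1e6, 1e6 + 100, 5e6, 9e6), H = H,
                       blockSizes = c(2L, 1L, 1L))
  vt <- variants(panel)
  none <- clumpLoci(rep(0.5, 4), vt, panel, threshold = 0.01)
  expect_identical(nrow(none), 0L)
  cf <- c(0.001, 0.005, 0.5, 0.002)
  loci <- clumpLoci(cf, vt, panel, r2Cut = 0.1, threshold = 0.01)
  expect_identical(nrow(loci), 2L)
  expect_identical(loci$lead[1], vt@id[1])  # smallest cfdr leads
  expect_identical(loci$nMembers[1], 2L)    # its duplicate joins the locus
  expect_identical(loci$lead[2], vt@id[4])
})
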