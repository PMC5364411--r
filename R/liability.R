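#' Liability threshold for a lifetime risk
#'
#' Under the liability-threshold model a binary trait with lifetime risk K
#' corresponds to a standard-normal liability exceeding
#' `t = qnorm(1 - K)`.
#'
#' @param K lifetime risk in (0, 1).
#' @return the liability threshold.
#' @examples
#' liabilityThreshold(1 / 400)  # ~2.807
#' @export
liabilityThreshold <- function(K) {
  if (any(K <= 0 | K >= 1)) stop("K must lie in (0, 1)")
  qnorm(1 - K)
}

#' Joint lifetime risk under the bivariate liability-threshold model
#'
#' The probability that both standard-normal liabilities, correlated with
#' liability-scale covariance `rhoLiab`, exceed their thresholds.  Computed
#' by reducing the bivariate-normal orthant probability to a one-dimensional
#' integral of the conditional survival function against the normal
#' density, evaluated by adaptive quadrature to absolute tolerance 1e-10.
#'
#' @param K1,K2 the two lifetime risks.
#' @param rhoLiab liability-scale covariance (equals the correlation, since
#'   liabilities have unit variance); |rhoLiab| < 1.
#' @return `P(L1 > t1, L2 > t2)`.
#' @examples
#' jointRisk(1 / 400, 1 / 100, 0)  # independence: 2.5e-5
#' @export
jointRisk <- function(K1, K2, rhoLiab) {
  if (abs(rhoLiab) >= 1) stop("|rhoLiab| must be < 1")
  t1 <- liabilityThreshold(K1)
  t2 <- liabilityThreshold(K2)
  s <- sqrt(1 - rhoLiab^2)
  f <- function(x) dnorm(x) * pnorm((t2 - rhoLiab * x) / s,
                                    lower.tail = FALSE)
  int <- integrate(f, t1, Inf, rel.tol = 1e-12, abs.tol = 1e-14,
                   subdivisions = 500L)
  if (int$abs.error > 1e-10)
    stop("orthant integration did not reach the requested tolerance")
  int$value
}

#' Comorbidity odds ratio under the bivariate liability model
#'
#' The odds ratio of the 2x2 table implied by the two marginal risks and
#' their joint risk: `OR = (p11 p00) / (p10 p01)`.  Symmetric in trait
#' order; equals 1 at `rhoLiab = 0` and increases with `rhoLiab`.
#'
#' @inheritParams jointRisk
#' @return the odds ratio.
#' @export
comorbidityOr <- function(K1, K2, rhoLiab) {
  p11 <- jointRisk(K1, K2, rhoLiab)
  p10 <- K1 - p11
  p01 <- K2 - p11
  p00 <- 1 - K1 - K2 + p11
  if (min(p10, p01, p00) <= 0) stop("degenerate 2x2 cell")
  (p11 * p00) / (p10 * p01)
}

#' Required misdiagnosis rate to explain a genetic covariance
#'
#' If the true genetic correlation were zero, the misdiagnosis rate of
#' trait-1 cases inside the trait-2 cohort needed to produce an observed
#' genetic covariance `rhoG` is `M = C / (C + 1)` with
#' `C = rhoG * nCases2 / nCases1`.
#'
#' @param rhoG liability-scale genetic covariance.
#' @param nCases2 cases in the cohort suspected of contamination (trait 2).
#' @param nCases1 cases in the source cohort (trait 1).
#' @return the misdiagnosis proportion.
#' @export
misdiagnosisRate <- function(rhoG, nCases2, nCases1) {
  if (nCases1 <= 0 || nCases2 <= 0) stop("case counts must be positive")
  C <- rhoG * nCases2 / nCases1
  C / (C + 1)
}

# Exact one-sample binomial power: smallest rejection count at level alpha
# under p0, then power under p1.
.binomPower <- function(n, p0, p1, alpha) {
  kCrit <- qbinom(alpha, n, p0, lower.tail = FALSE) + 1
  pbinom(kCrit - 1, n, p1, lower.tail = FALSE)
}

#' Required cohort size to detect excess comorbidity
#'
#' Smallest n for which a one-sample binomial test of rate `p0` against the
#' comorbid rate `p1 > p0` reaches the target power at level `alpha`.  The
#' normal-approximation sample-size formula provides the starting point and
#' an exact-binomial refinement pass scans around it.
#'
#' @param p0 baseline rate.
#' @param p1 comorbid (alternative) rate.
#' @param alpha test level (one-sided by default, per `sided`).
#' @param power target power.
#' @param sided 1 (default) or 2.
#' @return the required cohort size (integer).
#' @export
requiredCohortSize <- function(p0, p1, alpha = 0.05, power = 0.80,
                               sided = 1) {
  if (p0 <= 0 || p1 >= 1 || p1 <= p0) stop("need 0 < p0 < p1 < 1")
  a <- if (sided == 2) alpha / 2 else alpha
  za <- qnorm(1 - a); zb <- qnorm(power)
  n0 <- ceiling(((za * sqrt(p0 * (1 - p0)) + zb * sqrt(p1 * (1 - p1))) /
                   (p1 - p0))^2)
  n0 <- max(n0, 1)
  # exact refinement: binomial power is sawtoothed in n, so scan a
  # neighbourhood for the smallest n achieving the target
  lo <- max(1, floor(0.5 * n0)); hi <- ceiling(2 * n0) + 20
  while (.binomPower(hi, p0, p1, a) < power) {
    lo <- hi; hi <- 2 * hi
  }
  ns <- lo:hi
  pw <- vapply(ns, .binomPower, numeric(1), p0 = p0, p1 = p1, alpha = a)
  hit <- which(pw >= power)
  if (!length(hit)) return(hi)
  ns[hit[1]]
}

#' Full comorbidity analysis from cross-trait regression estimates
#'
#' Combines the bivariate liability-threshold model pieces: from a genetic
#' correlation (with optional confidence bounds), two liability-scale
#' heritabilities and two lifetime risks it computes the liability
#' covariance, joint lifetime risk, comorbidity odds ratio with plug-in
#' range, the required epidemiological cohort size (power of a binomial
#' test for excess trait-2 prevalence among trait-1 cases), and optionally
#' the misdiagnosis rate implied by the case counts.
#'
#' The odds-ratio and cohort-size ranges are obtained by plugging the
#' genetic-correlation confidence bounds into the model with the
#' heritabilities held fixed.
#'
#' @param rg genetic correlation point estimate.
#' @param h2Liab1,h2Liab2 liability-scale SNP heritabilities.
#' @param K1,K2 lifetime risks.
#' @param rgCi optional length-2 confidence bounds for `rg`.
#' @param nCases1,nCases2 optional case counts for the misdiagnosis rate.
#' @param alpha,power,sided binomial power-calculation settings.
#' @return a [ComorbidityResult-class].
#' @examples
#' comorbidityAnalysis(0.143, 0.082, 0.23, 1/400, 1/100,
#'                     rgCi = c(0.0705, 0.216))
#' @export
comorbidityAnalysis <- function(rg, h2Liab1, h2Liab2, K1, K2, rgCi = NULL,
                                nCases1 = NULL, nCases2 = NULL,
                                alpha = 0.05, power = 0.80, sided = 1) {
  rho <- rg * sqrt(h2Liab1 * h2Liab2)
  pj <- jointRisk(K1, K2, rho)
  orPt <- comorbidityOr(K1, K2, rho)
  nReq <- function(r) {
    rho_r <- r * sqrt(h2Liab1 * h2Liab2)
    p1 <- jointRisk(K1, K2, rho_r) / K1   # P(trait2 | trait1)
    if (p1 <= K2) return(NA_real_)
    requiredCohortSize(K2, p1, alpha = alpha, power = power, sided = sided)
  }
  orLo <- orHi <- nLo <- nHi <- NA_real_
  if (!is.null(rgCi)) {
    orLo <- comorbidityOr(K1, K2, rgCi[1] * sqrt(h2Liab1 * h2Liab2))
    orHi <- comorbidityOr(K1, K2, rgCi[2] * sqrt(h2Liab1 * h2Liab2))
    nHi <- nReq(rgCi[1])   # weaker correlation -> larger cohort
    nLo <- nReq(rgCi[2])
  }
  md <- if (!is.null(nCases1) && !is.null(nCases2))
    misdiagnosisRate(rho, nCases2, nCases1) else NA_real_
  new("ComorbidityResult", rhoLiab = rho,
      t1 = liabilityThreshold(K1), t2 = liabilityThreshold(K2),
      pJoint = pj, recipJoint = 1 / pj, orComorbid = orPt,
      orLo = orLo, orHi = orHi, nRequired = nReq(rg),
      nRequiredLo = nLo, nRequiredHi = nHi, misdiagnosisRate = md)
}
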