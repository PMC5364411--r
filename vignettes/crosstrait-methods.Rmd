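---
title: "Methods and design notes for crosstrait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for crosstrait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

crosstrait implements the statistical machinery for asking whether two
case–control traits — the motivating pair being amyotrophic lateral
sclerosis (ALS) and schizophrenia — share polygenic risk, what that
sharing implies clinically, and whether it could instead be an artifact
of cohort contamination.  This vignette records the models, the
parameter choices, and the design decisions that were genuinely open.

## The liability-threshold frame

Throughout, a binary trait with lifetime risk $K$ is modelled as a latent
standard-normal liability exceeding $t = \Phi^{-1}(1-K)$.  Two traits are
coupled through the liability-scale genetic covariance
$\rho_g = r_g\sqrt{h^2_1 h^2_2}$, where $h^2_t$ are liability-scale SNP
heritabilities and $r_g$ the genetic correlation.  The assumptions are
additivity of common-variant effects, normality of both liabilities, and
a covariance fully attributable to genetics — environmental covariance is
not modelled, so the comorbidity predictions are *genetic* expectations.

`jointRisk()` computes the upper-orthant probability of the bivariate
normal by reducing it to a one-dimensional integral of the conditional
survival function against the normal density,
$\int_{t_1}^\infty \phi(x)\,\bar\Phi\!\big((t_2-\rho x)/\sqrt{1-\rho^2}\big)\,dx$,
evaluated with adaptive quadrature to an absolute tolerance of $10^{-10}$
(the integrator's achieved error is checked and a failure raises rather
than returns).  This keeps the orthant probability deterministic and free
of any Monte-Carlo noise; the test suite cross-checks it against a
$10^7$-draw simulation.

The comorbidity odds ratio comes from the 2x2 table implied by
$(K_1, K_2, P(\text{both}))$.  Confidence ranges are *plug-in*: the
genetic-correlation confidence bounds are substituted with the
heritabilities held fixed, which mirrors how the parenthetical ranges in
the motivating analysis track the $r_g$ interval.  With the point
estimates ($r_g = 0.143$, $h^2 = 0.082/0.23$, $K = 1/400, 1/100$) the
model puts the odds ratio at 1.176 with plug-in range 1.084–1.275 and the
joint lifetime risk at 1 in 34,094.

Two numerical caveats worth recording.  First, evaluating the
misdiagnosis formula $M = C/(C+1)$, $C = \rho_g N_2/N_1$, at the point
estimates gives 5.08%, slightly above the 4.86% sometimes quoted for this
parameterization; the quoted figure is consistent with a schizophrenia
heritability near 0.21 rather than 0.23.  The package reports whatever
the user's inputs imply and does not attempt to back-solve anyone's exact
inputs.  Second, the required-cohort-size calculation
(`requiredCohortSize()`) uses the normal-approximation sample-size
formula only as a starting point and then scans an exact binomial power
curve, which is sawtoothed in $n$; the smallest $n$ reaching the target
power is returned.  One-sided $\alpha = 0.05$ and 80% power are the
defaults, with the sidedness exposed because conventions differ.

## LD score regression

`univariateLdsc()` fits $E[\chi^2_j] = a + (N h^2/M)\,\ell_j$ by weighted
least squares.  Weights multiply the over-counting term
$1/\max(\ell_j, 1)$ with the heteroskedasticity term
$1/(1 + N\hat h^2 \ell_j/M)^2$ and are iterated twice from an unweighted
pass, which reproduces the standard weighting scheme of the reference
implementations in spirit without importing them.  Constrained mode fixes
$a = 1$ by regressing $\chi^2 - 1$ through the origin — appropriate when
confounding is already controlled (for example by mixed-model association
statistics).  Chi-squares above 80x their mean are winsorized with a
logged count; on small synthetic panels a single variant can otherwise
dominate the fit.  Standard errors come from a delete-one-block jackknife
over (by default) 200 contiguous variant blocks, the convention the field
relies on; the block count is configurable and the suite verifies that
jackknife SEs track the empirical spread of the estimator within a factor
of 1.5.

`bivariateLdsc()` regresses $z_1 z_2$ on $\ell$ with a free intercept —
the intercept absorbs sample overlap, which is exactly why $r_g$
estimates are robust to shared controls — and divides by the component
heritabilities.  Because the $M/N$ scalings cancel,
$r_g = s_c/\sqrt{s_1 s_2}$ in slope units, and the jackknife replicates
recompute all three slopes on the same leave-block-out sets so the SE
refers to the full statistic.  Jackknife blocks with non-positive
component slopes are dropped with a warning; a non-positive full-sample
component heritability makes $r_g$ undefined and is reported as missing
with its reason.

For shared controls, the null correlation between the two traits'
z-scores is $N_s\sqrt{P_1P_2/((1-P_1)(1-P_2))}/\sqrt{N_1N_2}$
(`sharedControlNullCorr()`), derived from the score statistic with
binary phenotypes; it reduces to the simple $N_s/\sqrt{N_1N_2}$ at 50%
case fractions, which is how the balanced synthetic cohorts exercise it.

Liability conversion multiplies observed-scale estimates by
$K^2(1-K)^2/(P(1-P)\phi(\Phi^{-1}(1-K))^2)$; it is linear, so jackknife
SEs convert with the same factor.

## The synthetic generator: what it emulates, and what it does not

`simulateReferencePanel()` builds haplotypes block by block: within a
block each allele copies the previous variant's allele with probability
$\exp(-d/\mathrm{decayCm})$ ($d$ = map distance), otherwise it draws from
the variant's base frequency.  This yields monotone LD decay in map
distance and exactly independent blocks, which is all that LD score
regression, clumping and cFDR locus definition need — it makes no claim
to coalescent realism, recombination hotspots, allele-frequency spectra,
or imputation uncertainty (synthetic data are fully observed; there are
no INFO scores and no X chromosome).  Defaults (1 kb spacing at
1 cM/Mb, decay scale 0.02 cM, base frequencies uniform on 0.05–0.95)
give adjacent-pair $r^2 \approx 0.8$ falling to near zero across a
50-variant block.

`drawEffectSizes()` draws per-variant standardized effects from the
bivariate normal with variances $h^2_t/M_c$ and covariance $\rho_g/M_c$
over the causal subset ($M_c = M\cdot\mathrm{propCausal}$), using an
eigenvalue square root so the comonotone boundary $|r_g| = 1$ is exact.
`simulateLiabilityCohort()` ascertains cases by rejection sampling with a
configurable attempt budget (default $500\,n_\mathrm{cases}/K$), which
keeps the liability model exact at the cost of refusing infeasible
designs with a named deficit.  Population structure uses Balding–Nichols
stratum frequencies with a 20% per-allele remix rate — enough to make
principal components separate strata without destroying block LD.
Shared controls are literally the same individuals placed in both
cohorts.

The generator's default architecture is the study condition of the
motivating analysis: $h^2 = (0.082, 0.23)$, $r_g = 0.143$, lifetime risks
$(1/400, 1/100)$, 10% of variants causal.  Genotype-level tests, however,
run at desk scale: prevalences of 0.1–0.3, cohorts of hundreds, panels of
120–1,000 variants.  Rejection sampling at $K = 1/400$ with realistic
cohort sizes would need hundreds of millions of draws, so the stochastic
genotype-level properties (permutation nulls, PRS recovery, heterogeneity
power) are validated at moderate prevalence where the same mathematics
applies; the direct summary-statistic simulator
(`simulateSummaryStatsDirect()`) is what carries the full-scale
conditions ($M = 50{,}000$, $N = 36{,}052$ and $79{,}845$), since it
samples z-scores straight from the regression model's moment structure.
Passing tests therefore demonstrate correctness of the estimators under
the generative model, not robustness to the full messiness of real GWAS
(cryptic relatedness, imputation error, phenotype misclassification
beyond the modelled kind).

`structuredPermutation()` subdivides the PC1–3 space into equal-width
cubes ($\lceil n_\mathrm{cubes}^{1/3}\rceil$ cells per axis) and permutes
case–control labels only within cubes, preserving global and per-cube
case counts exactly.  Equal-width (rather than equal-occupancy) cells
were chosen because they are the literal reading of a spatial
subdivision and make the preserved-structure property easy to verify;
degenerate principal components trigger a fall back to fewer dimensions
with a warning.

## Polygenic risk scores

Two-round greedy clumping (250 kb / $r^2 > 0.5$, then 5,000 kb /
$r^2 > 0.2$) with ties in $p$ broken by (chrom, pos, id) makes the
retained set order-independent.  Scores are $\sum \beta_v d_{iv}$ over
retained variants passing each of the twelve discovery thresholds
($5\times10^{-8}$ … 0.5), with mean-dosage imputation of missing calls.
Strand-ambiguous (A/T, G/C) variants are dropped and a 1% MAF floor
applied; an INFO-score filter is accepted as an optional column and is a
no-op when absent.  The incremental Nagelkerke $R^2$ subtracts the
covariates-only baseline; the score term's p-value is the Wald test by
default, with the likelihood-ratio test behind a flag, matching the
reporting conventions of generalized linear models.  Decile odds ratios
use rank-based deciles with stable tie-breaking (the quantile boundaries
only need "near identical" counts), decile 1 as reference.  Principal
components enter the covariate set when their joint-model Wald p-value
falls below 0.0005 (a Bonferroni-style cutoff for 100 components).

## cFDR

The estimator is the empirical-cdf form
$\widehat{\mathrm{cFDR}}_i = p_{1i}\,\#\{p_{2j} \le p_{2i}\}/\#\{p_{1j}
\le p_{1i}, p_{2j}\le p_{2i}\}$ with inclusive ties, clipped to
$[p_{1i}, 1]$ — chosen over modelled mixture densities because it is
exactly testable against a brute-force double loop (the package computes
it with a Fenwick tree in $O(M\log M)$).  The clip to at least $p_{1i}$
guards against anti-conservative artifacts in near-singleton strata.
Conditioning statistics are first residualized on LD score
($\chi^2_\mathrm{resid} = \max(\chi^2 - \hat s\,\ell, 10^{-8})$) and
decorrelated against the primary trait's z-scores using the
shared-control null correlation
($z_\mathrm{adj} = (z_2 - c\,z_1)/\sqrt{1-c^2}$); the decorrelation
contract is a documented stand-in for the unpublished shared-control
algebra of the method's lineage and is validated by its calibration
properties, not against any specific locus list.

One calibration subtlety: under a *global* two-trait null the empirical
estimator does not control the FDR at $q$ — the variant with the
smallest primary p-value sits in a near-singleton stratum and its
estimate collapses toward $p_1$, so spurious sub-threshold values occur
in roughly 40% of null datasets at $q=0.05$.  This is inherent to the
estimator, not an implementation artifact.  The meaningful calibration
property — the one the test suite asserts over 50 seeds — is that when
the primary trait has genuine signal and the conditioning trait is
independent of it, the realized false-discovery proportion among
discoveries stays at or below $q$; conditioning on an irrelevant trait
neither helps nor hurts.  Under genuine pleiotropy, conditioning
recovers substantially more planted loci than the unconditional
estimator at the same threshold.

Residualization uses a floor of $10^{-8}$ on the residual chi-square.
Because the $\chi^2_1$ density piles up near zero, a sizeable fraction of
variants is floored whenever the per-variant polygenic term is large;
residualization therefore behaves as intended only in the weak-signal
regime (mean $\chi^2 \approx 1.1$, as in real GWAS), and the tests assert
an approximately-zero refitted slope in that regime rather than exact
removal.

## Heterogeneity (BUHMBOX-style) test

For independent risk alleles of trait A, the test aggregates
case-minus-control pairwise dosage correlation differences
$y_{ij} = (r^{\mathrm{case}}_{ij} - r^{\mathrm{ctl}}_{ij})\sqrt{N_\mathrm{eff}}$,
$N_\mathrm{eff} = (1/N_\mathrm{case} + 1/N_\mathrm{ctl})^{-1}$, with
weights $w_{ij} = \delta_i\delta_j/\sqrt{p_iq_ip_jq_j}$
($\delta = p' - p$, risk-allele frequencies in cases and controls) into
$S = \sum_{i<j} w_{ij}y_{ij}/\sqrt{\sum w_{ij}^2} \sim N(0,1)$.  An
odds-ratio-parameterized weight variant sits behind a flag; the two
orderings agree closely and the acceptance surface is calibration and
power, not a particular printed statistic.  Control correlations are
estimated from the paired control cohort rather than assumed zero.
Whether risk-allele frequencies come from the discovery cohort or an
external reference is left as configuration
(`selectRiskAlleles()` computes them from the supplied cohort).

## Problem sizes and runtime

The test suite and the reproduction script are sized for a single core:
summary-statistic simulations use $M = 50{,}000$ variants with 20
replicates for the headline recovery checks and $M = 10{,}000$–$20{,}000$
for estimator diagnostics; genotype-level pipelines use panels of
120–1,000 variants and cohorts of 300–800 individuals; the heterogeneity
null calibration uses 200 replicates of 80 variants x 500 individuals.
These sizes were chosen so each property is measured with enough
replication to be stable at the asserted tolerances while the whole
suite completes in a few minutes.

## Known limitations

* No partitioned/stratified LD score regression or annotation-specific
  enrichment; no conjunctional (both-trait) FDR; no gene mapping of loci.
* The comorbidity model ignores age structure, competing risks and
  differential mortality; its outputs are lifetime-risk statements under
  stationarity.
* The exact printed values that depend on consortium-scale data (the
  0.12% PRS variance at its original sample size, specific locus lists,
  the published misdiagnosis percentage and cohort-size figures) are not
  desk-reproducible; the package substitutes the monotonicity,
  calibration and oracle-equivalence properties described above.
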