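Package: crosstrait
Title: Cross-Trait Genetic Correlation, Comorbidity and Pleiotropy for GWAS
    Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cross-trait analysis of genome-wide association
    studies of two case-control traits: LD score calculation and univariate
    and bivariate LD score regression with block-jackknife standard errors
    and liability-scale conversion; polygenic risk scoring with two-round
    LD clumping, Nagelkerke pseudo-R2 and decile odds ratios; a bivariate
    liability-threshold model of expected comorbidity, misdiagnosis rates
    and required epidemiological cohort sizes; conditional false discovery
    rate discovery of pleiotropic loci with LD-score residualization and
    shared-control adjustment; and a heterogeneity (BUHMBOX-style) test
    that separates pleiotropy from cohort contamination. A synthetic GWAS
    generator produces haplotype panels with block LD, bivariate polygenic
    case-control cohorts with shared controls and population strata, and
    summary statistics, so every stage of the pipeline is testable without
    consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
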