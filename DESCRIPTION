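Package: igscca
Title: Group-Wise Sparse Canonical Correlation Analysis for Imaging Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An imaging-genetics analysis pipeline linking SNP dosages to
    covariate-adjusted cortical-thickness phenotypes. Implements genotype
    quality control (call rate, heterozygosity, identity-by-descent, minor
    allele frequency, exact Hardy-Weinberg test, imputation-quality filters),
    summary-statistic filtering with greedy LD clumping, an L1-constrained
    rank-1 sparse canonical correlation solver applied separately to
    amyloid-negative and amyloid-positive groups, elastic-net cross-group
    predictive validation with Hittner's test for dependent correlations,
    quasi-Bayesian causal mediation through binary amyloid status, and local
    Fisher-exact gene-set over-representation analysis. A synthetic cohort
    generator with planted canonical and mediation signals makes every stage
    testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    MASS,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
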