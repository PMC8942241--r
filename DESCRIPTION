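Package: qtlvar
Title: Unbiased Estimation of QTL Variance and Heritability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the genetic variance and heritability contributed by a
    quantitative trait locus (QTL) without the upward bias of the naive
    squared-effect estimator. Implements the moment estimator (squared fixed
    effect minus its squared standard error), the equivalent random-effect
    REML estimator with the QTL treated as a variance component alongside a
    polygenic kinship term, delta-method standard errors for the heritability
    ratio, goodness-of-fit measures (R-squared, adjusted R-squared, pseudo
    R-squared), linkage-disequilibrium-partitioned multi-locus variances, a
    genome-scan driver with Haley-Knott pseudo-marker imputation and
    Bonferroni-corrected Wald thresholds, and replicated simulation
    experiments for F2 and full-sib populations that quantify the bias of the
    squared-effect method.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'genodata.R'
    'io.R'
    'lmm.R'
    'estimators.R'
    'simulate.R'
    'scan.R'
    'qtlvar-package.R'
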