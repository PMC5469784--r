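Package: mvdep
Title: Benchmarking Missing-Value Imputation and Differential Expression
    Detection for Label-Free Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates label-free quantitative proteomics intensity matrices
    with abundance-dependent (missing-not-at-random) missing values, imputes
    them with mean, k-nearest-neighbour, abundance-distribution and
    multiple-imputation-by-chained-equations methods, detects differentially
    expressed proteins with Welch's t-test, a permutation test, the SAM
    d-statistic and a reproducibility-optimized test statistic, and scores
    every imputation-by-detection combination with confusion metrics, partial
    AUC, detection rate / mean rank and imputation-fidelity indexes
    (correlation, MAD, MSD). Includes an end-to-end, seed-reproducible
    benchmark grid driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
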