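Package: gestaar
Title: Gestational Epigenetic Age Acceleration Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Applies linear gestational epigenetic clocks to CpG beta-value
    matrices, summarizes clock accuracy, computes epigenetic age acceleration
    residuals (EAAR) adjusted for gestational age, cell-type composition and
    genetic ancestry, and identifies birth- and pregnancy-related correlates
    of acceleration by bootstrapped elastic-net regression with
    variable-inclusion-probability (VIP) stability selection and elbow-based
    model-size choice. Includes cross-cohort coefficient-transfer replication,
    cross-tissue concordance tests, and a synthetic-cohort generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
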