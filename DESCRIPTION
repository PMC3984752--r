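Package: gfsrisk
Title: Genetic Fuzzy System for Ordinal Clinical Risk Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Mines interpretable fuzzy association rules from labelled patient
    cohorts and turns them into an ordinal risk classifier. Numerical features
    are discretised into semi-trapezoidal/triangular fuzzy partitions by
    one-dimensional average-linkage agglomerative clustering; a genetic
    algorithm over per-feature bitmask chromosomes searches for rules
    maximising the mean of fuzzy support and confidence, one risk class at a
    time; prediction sums confidence-weighted firing strengths per class and
    takes the top-scoring risk level. Includes stratified cross-validation
    with per-class sensitivity/specificity, a synthetic cohort generator with
    planted ground-truth rules, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
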