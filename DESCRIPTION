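Package: pharmsurv
Title: Pharmacosurveillance Tools for Companion-Animal Prescription Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-level surveillance of pharmaceutical
    prescription in companion-animal electronic health records. Maps free-text
    product descriptions to a drug taxonomy with rule-based text mining,
    estimates prescription frequencies with cluster-bootstrap confidence
    intervals, computes the Prescription Diversity statistic (an adaptation of
    the Simpson diversity index) with practice-level quintile benchmarking,
    and builds co-prescription networks with label-propagation group
    detection. Ships a synthetic electronic-health-record generator with known
    ground truth so every stage can be exercised and validated without access
    to confidential practice data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    stringr,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
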