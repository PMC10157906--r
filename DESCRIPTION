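Package: siap
Title: Weighted Set-Similarity Identification of Standard Sub-Prescriptions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Matches complex multi-drug prescriptions to the standard or
    classical sub-prescriptions they contain using weighted per-level
    overlap distances (the SIAP algorithm) against a formulary whose drugs
    are graded chief/deputy/assistant/envoy (C1-C4).  Includes the
    intersection-set-rate (ISR) baseline, training of the level weights by
    standardized logistic-regression coefficients, bootstrap grid search
    for the similarity threshold, micro-averaged multi-label evaluation,
    and a seeded synthetic generator of formularies and labelled clinical
    prescriptions for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
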