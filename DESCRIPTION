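Package: persotx
Title: Optimization of Personalized Combinatorial Cancer Therapies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Designs personalized combinatorial cancer therapies by assigning
    companion biomarkers and non-degenerate Boolean decision rules to a drug
    catalog so that the cohort-wide overall response rate is maximized under a
    bounded combination size. Includes the response-by-marker approximation
    with small-group shrinkage, a pharmacokinetic response model mapping
    logIC50 drug-sensitivity screens to response probabilities through the
    complementary error function, doubly-weighted nearest-neighbour imputation
    of missing logIC50 values with correlation-based parameter selection,
    multi-restart simulated annealing over marker assignments and Boolean
    protocols, and synthetic cohort generators with planted marker effects for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
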