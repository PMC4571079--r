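Package: cytoscreen
Title: Biomarker-Phenotype Association and Threshold-Rule Screening Tools
    for Flow-Cytometry Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for associating gated flow-cytometry population
    expressions with a binary clinical phenotype and for designing simple
    screening rules from the result. Variable importance is estimated with a
    conditional-inference forest (hypothesis-testing split selection,
    out-of-bag permutation importance, averaged over multiple seeded runs);
    coordinated sets of cytometry variables are scored with a feature-set
    enrichment random walk whose significance is assessed by phenotype
    permutation; and parsimonious any-out-of-bounds threshold screening
    tools are designed by stochastic search, optionally after Gini-based
    recursive pre-partitioning of patients into subgroups. Includes a
    seeded synthetic-cohort generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    rpart
Config/testthat/edition: 3
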