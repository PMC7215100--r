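Package: repotriad
Title: Classification and Network Analysis of Drug Repositioning Cases
Version: 0.1.0
Authors@R:
    person("repotriad", "maintainers", email = "maintainers@repotriad.org",
           role = c("aut", "cre"))
Description: Classifies drug-target-indication repositioning cases into
    disease-centric, target-centric, and drug-centric categories using a
    step-wise rule set (shared top-level MeSH disease key, shared or
    orthologous protein target, residual), scores candidate ortholog target
    pairs with exact Needleman-Wunsch global alignment and a BLOSUM62-based
    percent-identity statistic, and characterises each category's tripartite
    drug-target-indication network with clustering, transitivity, effective
    diameter, and a small-world score. Includes a curated 128-case corpus,
    a synthetic corpus generator with planted class labels for validation,
    contingency and category reporting, and an offline structural-coverage
    check against a local drug-target complex table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
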