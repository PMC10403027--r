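Package: CarePathways
Title: End-of-Life Care-Pathway Sequence Analysis and Spending Decomposition
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building and analysing daily care-state sequences over
    the last year of life from claims-like data: optimal-matching and
    longest-common-subsequence dissimilarities between 365-day state
    sequences, Ward hierarchical classification into care-pathway clusters,
    chronogram and index-plot summaries, and decomposition of last-year-of-life
    medical spending by service category, time window, expenditure decile and
    pathway cluster. Includes a synthetic decedent-cohort generator (cohort
    characteristics, noisy archetype state sequences with ground-truth labels,
    and costed service claims) so the full pipeline can be exercised and
    validated without access to confidential claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    arrow,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
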