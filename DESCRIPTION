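Package: lcq
Title: QTL Mapping in Two-Line Crosses
Version: 0.1.0
Authors@R:
    person("lcq", "developers", email = "lcq@example.org", role = c("aut", "cre"))
Description: Quantitative trait locus (QTL) analysis for experimental crosses
    between two (possibly outbred) founder lines. Provides a hidden Markov
    model for posterior line-origin probabilities along a grid of genome
    positions, Haley-Knott least-squares genome scans (single locus and
    two-locus epistasis) with Churchill-Doerge permutation thresholds,
    orthogonal genetic-effect estimation under the NOIA parameterisation
    with change-of-reference machinery, Monte-Carlo identity-by-descent
    matrix estimation, and a variance-component score-statistic analysis
    (flexible intercross analysis) for QTL that segregate within the
    founder lines. A cross simulator with fully recorded descent truth
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
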