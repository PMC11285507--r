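Package: structdiv
Title: Structural Diversity of Networks via Random-Walk Meeting Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies a network's propensity to sustain cultural diversity
    under neutral imitation-innovation dynamics. Implements the structural
    diversity index (the expected meeting time of two synchronous random
    walks divided by the vertex count), a right-censored geometric estimator
    of the meeting time, an exact small-graph pair-chain oracle, the
    synchronous voter model with innovation (infinite alleles) and its
    Simpson-diversity trajectory, closed-form index predictions and bounds
    for complete, power-law and Watts-Strogatz networks, and a
    degree-targeted edge-removal intervention that raises the index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
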