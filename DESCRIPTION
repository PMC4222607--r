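Package: boolgrn
Title: Boolean Threshold Gene Regulatory Networks: Stability, Robustness
    and the Evolution of Autoregulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulator and analysis toolkit for Boolean threshold gene
    regulatory networks (random threshold networks). Genes carry binary
    (+1/-1) expression states updated synchronously through a signed
    interaction matrix; development iterates the map to a fixed point or
    limit cycle. The package provides exact attractor detection, network
    generators (random, sign-composition-controlled, pre-selected stable,
    engineered, and sparse regular), sign-of-autoregulation statistics
    (p, q, and the indirect length-two statistic r), single-mutant
    viability and robustness scans, a Wright-Fisher evolutionary engine
    with four selection models, mutation and row-segregation
    recombination, and reproducible experiment recipes for stability,
    robustness and conservation analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
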