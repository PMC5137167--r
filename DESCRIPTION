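Package: netcomplexity
Title: Functional Complexity of Network Dynamics on Structural Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic mapping from binary structural connectomes to functional
    connectivity via linear-Gaussian and communicability (matrix exponential)
    propagators, a functional-complexity statistic on the distribution of
    pairwise correlations, generators for random, scale-free, modular and
    hierarchical-modular networks (including a centralised hierarchical-modular
    model whose cross-modular links are routed through rich-club hubs),
    degree- and modularity-preserving surrogate randomisations, rich-club
    detection, and experiment drivers for coupling scans, surrogate
    comparisons, rich-club lesion studies and empirical functional-connectivity
    fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
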