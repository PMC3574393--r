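Package: modcost
Title: Evolution of Modular Networks Under Connection Costs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational evolution of layered feed-forward networks on
    pattern-recognition (retina) and Boolean (XOR) tasks, comparing selection
    on performance alone with multi-objective selection that also minimizes
    connection costs (summed squared wiring length under optimal node
    placement, or connection count). Implements NSGA-II with stochastic
    Pareto dominance, directed network modularity Q with exact and heuristic
    maximization, functional-modularity diagnostics, evolvability-transfer
    experiments, modularly varying goals, and the Multi-Objective Landscape
    Exploration (MOLE) algorithm for mapping best achievable performance over
    the cost-modularity plane.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    xml2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
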