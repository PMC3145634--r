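Package: costnet
Title: Cost-Integrated Topological Analysis of Weighted Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Separates connectivity strength from topology when comparing
    weighted undirected networks, such as functional brain connectomes built
    from association matrices. Provides percentile-rank thresholding of a
    weighted network at every achievable wiring cost, unweighted topological
    metrics (global and local efficiency) integrated against user-chosen
    distributions over the discrete cost grid (uniform, Beta-binomial,
    interval-conditioned), exact and Monte-Carlo evaluation of the integrals
    with standard errors and convergence traces, and weighted cost and
    weighted efficiency for comparison. Includes generators for layered
    regular/random association matrices and other synthetic fixtures, plus
    delimited-text input/output for dense matrices and edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'network-core.R'
    'thresholding.R'
    'efficiency.R'
    'distributions.R'
    'integration.R'
    'monte-carlo.R'
    'synthetic.R'
    'io.R'
    'cli.R'
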