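Package: nimclass
Title: Node-Influence Classification for Gene Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transductive classification of high-dimensional, small-sample
    gene expression profiles on Gaussian similarity graphs. Implements a
    walk-count node-influence centrality (the large-k limit of the fraction
    of k-length walks ending at any node that start from a given node,
    equal to the normalized leading-eigenvector component for connected
    non-bipartite graphs) and two influence-weighted similarity classifiers
    (NIM1 with one kernel bandwidth, NIM2 with separate bandwidths for the
    influence graph and the class-scoring step). Includes leave-one-out and
    holdout evaluation, bandwidth grid search, convergence diagnostics, a
    synthetic expression-data generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
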