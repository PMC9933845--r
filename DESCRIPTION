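Package: phyplace
Title: Divide-and-Conquer Maximum-Likelihood Phylogenetic Placement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood placement of aligned query sequences onto a
    fixed backbone phylogeny under the GTR+Gamma substitution model. Provides
    Felsenstein-pruning likelihood computation with two-directional partial
    caching, branch-length and model-parameter estimation on a fixed topology,
    per-edge query placement with attachment-geometry optimization, a
    divide-and-conquer layer that restricts placement to a subtree around the
    query's nearest leaf (by normalized Hamming distance) and maps the result
    back onto the backbone, jplace output, and an evaluation suite
    (missing-branch counts, delta error, leave-one-out experiments,
    fragmentary-query protocols) backed by a synthetic tree and sequence
    simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    Matrix,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
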