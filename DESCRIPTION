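Package: phylopart
Title: Partitioned Maximum-Likelihood Supermatrix Phylogenomics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Partitioned maximum-likelihood analysis of multigene nucleotide
    supermatrices. Implements JC, HKY and GTR (REV) substitution models with
    discrete-gamma rate heterogeneity, Felsenstein pruning with per-node
    scaling, coordinate-ascent parameter and branch-length optimization,
    codon-position sharing schemes (branch-length scaling factors through
    fully separate parameter sets), per-gene partitioned fitting over
    exhaustively enumerated candidate tree sets, hierarchical likelihood
    ratio tests, per-partition small-sample AIC (AICc) and BIC, RELL and
    nonparametric bootstrap support, Robinson-Foulds gene-tree congruence
    diagnostics, and a forward simulator of heterogeneous multigene data
    with known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
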