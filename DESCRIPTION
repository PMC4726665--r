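Package: metamodule
Title: Network-Based Meta-Analysis of Multi-Study Gene Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Combines differential-expression evidence across multiple
    two-group microarray studies and integrates it with a protein-protein
    interaction network to detect consensus functional modules. Per-study
    significance is assessed with the SAM relative-difference score and
    permutation p-values; genes are merged across studies by Fisher's
    p-value combination and by fixed/random-effects pooling of
    standardized mean differences with Cochran's Q / I-squared
    heterogeneity gating. Combined p-values are converted to additive
    node scores through a beta-uniform mixture model, the maximum-scoring
    connected subnetwork is extracted (exact branch-and-bound or
    heuristic), and a consensus module is built by resampling. Includes
    hypergeometric pathway enrichment, candidate-gene selection,
    gene-level GWAS lookup, and a synthetic multi-study data generator
    with a planted differential module for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
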