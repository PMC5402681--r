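Package: micam
Title: Optimal Microbiome-Based Association Testing and Comprehensive
    Taxonomic Association Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adaptive association testing between microbial community
    composition and continuous or binary host traits. Implements the sum of
    powered score (SPU) tests on standardized compositions, kernel-machine
    variance-component score tests (MiRKAT) over a candidate set of
    Bray-Curtis and UniFrac-family distance kernels, and their min-P
    combination (OMiAT) under a single shared permutation null.  A
    comprehensive association mapping framework (MiCAM) scans every taxon at
    every taxonomic rank from kingdom to species with per-rank
    Benjamini-Hochberg false discovery rate control and renders a
    hierarchical discovery map.  Includes a Dirichlet-multinomial synthetic
    data generator and the type-I-error / power experiments used to validate
    the tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    biomformat,
    cluster,
    ggplot2,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
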