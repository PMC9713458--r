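Package: xqtl
Title: Extreme-QTL Mapping from Pooled Sequencing of Multiparent Populations
Version: 0.1.0
Authors@R:
    person("Ingrid", "Halvorsen", email = "ingrid.halvorsen@example.org",
           role = c("aut", "cre"))
Description: Tools for extreme-QTL (X-QTL) bulk-segregant mapping in
    multiparent populations. Estimates founder haplotype frequencies of
    pooled-sequenced samples in sliding genetic-map windows by constrained
    weighted least squares on the simplex, scans the genome for
    treatment-driven haplotype frequency differentiation with a replicated
    ANOVA on arcsine square-root transformed frequencies, calls QTL with
    LOD-drop confidence intervals, and ships a synthetic multiparent
    population simulator (recombinant founder mosaics, truncation selection
    at planted causal loci, binomial pooled reads) so the whole pipeline can
    be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
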