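Package: popmicrodiv
Title: Intrapopulation Microdiversity, Recruitment and Recombination Metrics
    from Metagenomic Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Codon-aware population-genetic statistics for sequence-discrete
    prokaryotic populations observed through metagenomic read recruitment:
    per-gene nonsynonymous and synonymous polymorphism rates (pN, pS, pN/pS),
    percentage of polymorphic sites, normalized abundance (RPKG), read-based
    average nucleotide identity (ANIr), correlation-profile estimates of the
    recombination-to-mutation ratio (gamma/mu) and recombination coverage (c),
    and gene-tree congruence against a concatenated phylogeny. Includes a
    lineage-structured population and shotgun-read simulator with full ground
    truth, so every estimator can be validated by parameter recovery without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    IRanges,
    rtracklayer,
    ape,
    phangorn,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
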