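Package: strainmap
Title: Strain-Level Taxonomic Assignment and Abundance Estimation for
    Long Metagenomic Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Taxonomic classification of long (>1 kb) metagenomic
    sequencing reads against a reference genome database at strain-level
    resolution. Candidate mapping locations are found with a winnowed
    minimizer index, alignment identity is estimated with a
    winnowed-minhash statistic, mapping locations are scored with a
    probabilistic (binomial) mapping-quality model, and overall sample
    composition is estimated jointly with per-read placements by an
    EM algorithm with a composition-dependent prior. Includes a
    memory-limited chunked indexing mode, read-, base- and
    composition-level evaluation metrics against truth sets, per-genome
    identity and coverage diagnostics, gene-annotation overlap counting,
    and a pbsim-style long-read simulator for building fully synthetic
    test communities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
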