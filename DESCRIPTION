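Package: pathosig
Title: Pan-Pathogen Microarray Signatures and Viral Integration Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for pan-pathogen detection microarrays and
    capture sequencing of tumour tissue. Normalizes two-channel probe
    signals against human reference probes, detects differential microbial
    hybridization signatures between cancer and control groups with
    Benjamini-Hochberg control, aggregates probe signals to taxa and
    families with per-group prevalence, partitions signature sets across
    sample groups, clusters samples by hierarchical clustering with
    Calinski-Harabasz selection of the cluster number, and calls viral
    integration breakpoints in a host genome from soft-clipped read
    alignments with gene-context annotation. Includes synthetic-data
    generators for arrays and chimeric reads with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    tools,
    Rcpp,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    ape,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
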