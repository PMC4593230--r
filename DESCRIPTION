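Package: longotu
Title: OTU Inference for Long-Read 16S rRNA Amplicons by Pairwise
    Alignment and Hierarchical Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Clusters 16S rRNA gene amplicon reads into operational
    taxonomic units (OTUs) using all-versus-all Needleman-Wunsch global
    alignments with post-processing tailored to PacBio circular consensus
    (CCS) reads (terminal-gap removal and collapsing of single-base
    indels, the dominant CCS error mode), followed by complete-linkage
    hierarchical clustering with threshold cutting. Includes read
    preprocessing (pair merging, quality-fraction and length filtering,
    barcode demultiplexing), a mock-community benchmark generator with
    short-read and CCS error models, adjusted-Rand-index evaluation of
    clustering quality, Shannon-entropy profiling of hypervariable
    regions, and a mixed-technology sub-OTU refinement workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    methods,
    parallel,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    seqinr
Config/testthat/edition: 3
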