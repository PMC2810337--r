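Package: musselEST
Title: Multi-Tissue EST Transcriptome Profiling for Mytilus galloprovincialis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a multi-tissue expressed sequence
    tag (EST) profiling workflow for the Mediterranean mussel. Simulates
    MID-barcoded 454-style cDNA reads from a fully specified synthetic
    reference (mitochondrial genome with annotations, nuclear and bacterial
    transcripts with marker classes), demultiplexes the pooled reads by
    barcode, assembles each tissue bin with a greedy overlap-consensus
    assembler, recruits raw reads to the mitochondrial genome as
    coordinate-by-identity heat maps with Smith-Waterman local alignment and
    Karlin-Altschul E-values, and derives the downstream summaries: per-gene
    normalized abundance, all-against-all contig homology, marker-based
    sex-ratio estimation, taxonomic and subsystem profiles, Margalef
    richness, Bray-Curtis dissimilarity and nonmetric multidimensional
    scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vegan,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
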