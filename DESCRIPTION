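Package: umisplice
Title: Splice-Graph Transcript Assembly for UMI-Based Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reference-guided full-length transcript assembly for single-cell
    RNA-seq protocols that mix UMI-linked 5' reads with un-tagged internal
    reads (e.g. Smart-seq3). Reads are classified by the UB alignment tag,
    PCR duplicates are collapsed, junction-free internal reads inherit
    strandness from nearby UMI-supported loci, and contaminated loci are
    purged. Each locus is assembled through a weighted splice graph with
    rule-based pruning of full and partial intron retentions and isolated
    intronic vertices, phase-preserving path decomposition, and UMI
    anchoring of first exons. Includes a pooled ("super-cell")
    meta-assembly mode, an intron-chain evaluation module, and a
    deterministic synthetic-data generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
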