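Package: tagdge
Title: Tag-Based Digital Gene Expression and Small RNA Profiling of Matched
    Tumor/Normal Libraries
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrated analysis pipeline for tag-based digital gene
    expression (NlaIII/DGE) and small RNA sequencing of matched tumor/normal
    pairs. Builds a virtual CATG+17nt tag reference, filters and maps raw
    tags with at most one mismatch requiring unique hits, normalizes to tags
    per million (TPM), and tests per-pair differential expression with the
    exact Audic-Claverie count statistic under Benjamini-Hochberg false
    discovery rate control. Small RNA reads are adapter-clipped by dynamic
    programming, deduplicated, assigned through a fixed annotation hierarchy,
    and screened for novel miRNA hairpin candidates by stem-loop folding,
    free-energy and cross-sample recurrence criteria. Downstream modules
    provide right-sided hypergeometric gene-set enrichment, gene set
    enrichment analysis (GSEA) with leading-edge core-gene and miRNA-target
    prioritization, and positional enrichment scanning of genomic miRNA
    clusters. A first-class synthetic-data generator emulates the matched
    10-pair study design with a machine-readable truth record so every stage
    is testable against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    fgsea,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
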