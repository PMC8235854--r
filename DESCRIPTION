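Package: chromdyn
Title: Integrative Analysis of Chromatin State Dynamics and Transcription
    Factor Regulation Across Differentiation Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of multi-stage ChIP-Seq and RNA-Seq
    experiments in a differentiating lineage: quality filtering and
    gene annotation of called peaks, construction of bivalent
    (H3K4me3 + H3K27me3) chromatin domains and per-gene promoter state
    calls with cross-stage transition dynamics, integration of
    transcription-factor binding with differential expression to label
    putative activated and repressed targets, k-means expression pattern
    discovery and Z-score cell-type specificity, guilt-by-association
    lncRNA function prediction built on a preranked gene set enrichment
    core with permutation-based normalized enrichment scores and FDR,
    and RIP-Seq target screening with AU-rich element scanning.  A
    seeded synthetic-data generator with planted ground truth makes the
    whole pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
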