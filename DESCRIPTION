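Package: bsdmr
Title: Two-Sample Differential Methylation Analysis for Whole-Genome
    Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Window-based differential-methylation-region (DMR) calling for
    two-sample whole-genome bisulfite sequencing, and integration of the
    resulting regions with gene expression. Parses Bismark-style cytosine
    reports, classifies CG/CHG/CHH sequence context from a reference
    genome, computes per-cytosine methylation levels under a coverage
    filter, calls DMRs by pooled-count Fisher exact tests with a
    fold-change criterion and iterative merging, associates DMRs with gene
    bodies and 2-kb promoters, classifies hyper/hypo x up/down methylated
    differentially expressed genes, and performs hypergeometric term
    enrichment with Benjamini-Hochberg correction. Includes a synthetic
    methylome and expression simulator with full ground truth so every
    stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
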