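Package: haloTSS
Title: Primary Transcriptome Analysis from Differential RNA-Seq in Haloarchaea
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls transcriptional start sites (TSSs) from strand-specific
    5'-end coverage of TEX-treated and untreated dRNA-Seq libraries,
    classifies them against a genome annotation (leaderless, leadered,
    known RNA, intergenic, internal, antisense), derives a basal-promoter
    position weight matrix by iterative positional refinement with exact
    p-value score thresholds, and runs the downstream 5'-UTR, start-codon,
    upstream-ORF, small-protein and sense/antisense analyses. Includes a
    synthetic-data generator that emulates a GC-rich archaeal genome with
    planted promoters, leaderless-dominant gene starts and TEX enrichment,
    so the whole workflow is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
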