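Package: rloopenrich
Title: R-Loop Forming Sequence Prediction and Gene-Set Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying R-loop forming sequences (RLFS) and their
    relationship to stress-responsive gene expression. Predicts RLFS on both
    strands of nucleotide sequence with an explicit RIZ/REZ model, merges
    overlapping predictions, and computes per-gene RLFS density metrics
    (RLFS per kb and percent coverage) on promoter/terminator-flanked gene
    windows together with gene features (length, exon count, GC percent,
    G-quadruplex motifs). Compares differentially expressed gene sets against
    the protein-coding background with a resampling enrichment test, calls
    differential expression with the rank-product statistic and
    permutation-based false-prediction proportions, scores metagene
    signatures by median panel expression and Spearman correlation, and
    quantifies common bench assays (DNA fibre replication rates, delta-delta-Ct
    fold changes, focus-positive cell fractions). A synthetic-data generator
    with recorded ground truth makes every stage testable end to end, and a
    pipeline driver orchestrates the full analysis reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
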