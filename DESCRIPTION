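Package: clonotrack
Title: Paired-Chain TCR Clonality and Single-Cell Expression Analysis of
    Serial Allograft Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Combined single-cell transcriptome and paired-chain TCR
    clonality analysis for serial kidney-allograft biopsies and urine
    sediment: per-cell quality control and log-normalization, marker-based
    CD8+ T-cell selection, clonotype calling on identical CDR3 alpha/beta
    sequences with a more-than-two-cells expansion rule and dual TCR-alpha
    accounting, longitudinal clone tracking across time points, biopsy-urine
    clonal overlap, and Wilcoxon rank-sum differential expression between
    expanded and unexpanded clonotypes or treatment arms. Includes a
    synthetic cohort generator emitting 10x-style V(D)J and gene-expression
    files with planted clonal ground truth, so every stage is testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
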