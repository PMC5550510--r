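Package: votesig
Title: Vote-Counting Consensus Transcriptional Signatures Across Injury Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for cross-model transcriptome
    meta-analysis by direction-specific vote counting. Expression tables are
    log2-transformed and quantile normalized; per-contrast differential
    expression is called with a fold-change filter plus an expression floor;
    genes dysregulated in at least a minimum number of independent contrasts
    form the consensus signature. Downstream stages provide gene-set
    enrichment (exact hypergeometric and EASE statistics with
    Benjamini-Hochberg correction), promoter-proximal known-motif enrichment
    by position-weight-matrix scanning, and exact small-sample Wilcoxon
    signed-rank and Mann-Whitney tests. A synthetic-data generator plants
    known consensus genes, promoter motifs, and enriched gene sets so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    tools,
    utils,
    yaml,
    withr,
    Biostrings,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
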