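Package: tealseq
Title: Targeted Expression Analysis with Multiplexed Probe Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design and analysis toolkit for highly multiplexed,
    species-specific expression-targeting probe panels in mixed microbial
    communities. Designs 40-mer single-primer-extension (SPE) and dual-arm
    molecular inversion probe (MIP) panels from pangenome presence/absence
    data with thermodynamic, compositional, inclusion/exclusion and
    host-transcriptome specificity screens; quantifies captured reads into
    probe-level CPM and CDS-level RPKM tables with method-specific alignment
    filters; calls differentially expressed genes from the median of
    per-probe negative-binomial tests; and ships a seeded simulator of
    pangenomes, expression states and probe-captured reads so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils,
    MASS,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    BiocGenerics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
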