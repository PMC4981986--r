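Package: repeatscape
Title: Repeat-Driven Genome Compartmentalization and Repeat-Gene-Methylation
    Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the repetitive fraction of a plant genome
    and its relationship to genes, DNA methylation and transcription-factor
    binding. Provides strict k-mer repeat detection with annotation-layer
    merging, windowed coverage profiles partitioned into repeat-rich,
    intermediate and repeat-poor compartments by k-means, TE-gene filtering
    by CDS coverage, a gene/repeat/DMR/RIN-peak interval association engine,
    categorical enrichment statistics (expected counts, chi-square with
    Bonferroni correction, Mann-Whitney rank tests, Monte-Carlo placement
    nulls), and a seeded synthetic annotated-genome generator so the full
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomeInfoDb,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
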