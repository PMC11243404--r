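Package: venomreg
Title: Regulatory Correlates of Venom Gene Expression Across Rattlesnake Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative comparative-genomics toolkit linking venom gene
    expression variation to regulatory-feature variation across closely
    related rattlesnake lineages. Implements median-of-ratios count
    normalization, venom-gland replicate combining, expression variance
    analysis and significance-filtered transcription-factor to venom-gene
    correlation networks; centered-log-ratio coupling of transcriptome and
    proteome; nucleotide diversity and variant-induced transcription factor
    binding site gain/loss at cis-regulatory elements; ATAC-seq footprint
    binarization and occupancy counting; windowed read-depth deletion
    evidence; and a phylogenetic-contrast principal-component regression
    that produces a per-gene matrix of regulatory correlates. A seeded
    synthetic-data generator emits a complete, internally consistent input
    bundle with known ground truth so the whole pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    ape,
    vcfR,
    Biostrings
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
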