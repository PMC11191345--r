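Package: sexscan
Title: Detecting Sex-Linked Genomic Regions from Expression, Coverage and
    k-mer Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decides whether a gonochoristic species carries sex-specific
    genomic regions by combining three evidence channels: sliding-window
    Fisher enrichment of strongly sex-biased transcripts, sex-compared
    median-normalized genomic coverage (hemizygosity scan), and a per-contig
    k-mer sex-specificity scan (percent validated single-copy unmatched
    k-mers, P_VSC_UK) run in both XY and ZW directions. Ships a synthetic
    data generator that simulates XY, ZW and no-sex-chromosome genome
    architectures with machine-readable ground truth so each stage's
    detection behavior is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
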