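Package: poolscan
Title: Mapping-by-Sequencing of Pooled F2 Samples with the Euclidean-Distance Scan
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Bulked segregant analysis of pooled whole-genome sequencing data
    from an F2 mapping population. Computes the per-variant Euclidean distance
    between the nucleotide-frequency vectors of two phenotype-selected pools,
    smooths the profile along each chromosome, calls candidate regions against
    a median + 3 SD threshold, classifies variant effects against gene models,
    applies the homozygous-differential filter that shortlists causal
    candidates, and predicts the transcript and protein consequences of splice
    donor-site mutations (intron retention and cryptic-donor partial exon
    deletion). Includes a simulator of EMS-mutagenized F2 pooled-sequencing
    experiments with known ground truth, segregation chi-square testing, and
    CAPS/dCAPS restriction-digest genotyping logic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    GenomicRanges,
    vcfR,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
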