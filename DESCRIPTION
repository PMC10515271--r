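Package: hlbscreen
Title: Candidate Screening for DNA-Binding Factors at a Tandem Histone Gene Array
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening ChIP-seq datasets for DNA-binding factors at
    the Drosophila replication-dependent histone gene array. The ~100 nearly
    identical 5 kb repeat units of the histone locus are collapsed onto a
    single repeat-unit reference; reads are mapped with an internal circular
    k-mer mapper, per-base (1 bp bin) coverage is computed, ChIP signal is
    normalized to input as a depth-scaled log2 ratio, and each ChIP/input pair
    is classified as positive or negative by a peak-emergence criterion plus
    four false-positive rules (gene-body overrepresentation, intergenic
    depletion, input-identical signal, and short-read GA-repeat multimapping
    pileups), with peak-to-element localization. A synthetic-data module
    generates tandem-repeat references and seeded ChIP/input read sets with
    ground truth under the enrichment and artifact modes the classifier
    distinguishes, so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges,
    IRanges,
    Rsamtools,
    rtracklayer
Config/testthat/edition: 3
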