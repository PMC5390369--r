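Package: methwind
Title: Sliding-Window Methylome Analysis for Whole-Genome Bisulfite
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Context-stratified analysis of whole-genome bisulfite
    sequencing count tables: classification of cytosines into CG, CHG and
    CHH contexts on both strands, estimation of the bisulfite
    non-conversion rate from an unmethylated lambda spike-in, raw and
    non-conversion-corrected methylation levels, binomial calling of
    methylated sites with false-discovery-rate control, sliding-window
    pooling of counts, Fisher-exact-test detection of differentially
    methylated regions between conditions, gene-element metaprofiles,
    methylation-versus-expression normalisation, sequence-preference
    matrices around methylcytosines, and a CpG-island-style site
    predictor. Includes a synthetic bisulfite count generator with
    planted differentially methylated regions and a known non-conversion
    rate so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr (>= 1.1.0),
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
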