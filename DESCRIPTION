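Package: epicleave
Title: In-Silico MassCLEAVE Assay Design and Quality Control for
    Bisulfite Methylation Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mass-spectrometry-based, region-specific DNA
    methylation assays. Simulates the T-cleavage biochemistry applied to
    bisulfite-PCR amplicons (bisulfite conversion, reverse-strand
    transcription, uracil-specific RNA cleavage) and predicts fragment
    masses, so that candidate amplicons can be evaluated for measurable
    CpG units, mass collisions and bisulfite conversion controls before
    any wet-lab work. Also provides the downstream quality-control
    pipeline that turns exported triplicate measurement grids into a
    clean sample-by-CpG-unit methylation matrix (replicate collapsing,
    standard-deviation and success-rate filters, overlap and SNP
    removal, multimodality checks), a 384-well plate designer, and a
    synthetic-data generator with known ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
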