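Package: tfrepair
Title: Damage Formation and Excision Repair Profiling at Transcription
    Factor Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for single-nucleotide DNA damage mapping and base
    excision repair analysis from lesion-tagged sequencing libraries
    (NMP-seq, CPD-seq). Infers strand-specific lesion positions from
    aligned-read 5' ends, normalizes cellular damage to naked-DNA
    controls to obtain damage-formation profiles, computes fractions of
    remaining damage across repair time courses (optionally spike-in
    corrected), and aggregates signal around oriented transcription
    factor binding sites and transcription start sites, with occupancy
    stratification, target-gene linkage, nucleosome overlays, and
    repair-inhibition width estimation. Ships a synthetic-data generator
    with planted ground truth so every stage is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
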