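Package: psistop
Title: Transcriptome-Wide Pseudouridine Discovery from Reverse-Transcription Stop Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls pseudouridine (Psi) sites transcriptome-wide from
    CMC-dependent reverse-transcription stop profiles. Takes per-position
    read 5'-end count tracks for CMC-treated, mock-treated, and
    synthase-knockout libraries, computes a 95%-winsorized Z-score over a
    transcript-end-aware 100-nt background window for every uridine,
    applies a CMC-dependence decision rule, and assigns called sites to
    pseudouridine synthases via knockout signal loss. Also provides
    pooling/subsampling saturation analysis, sequence-motif and codon
    context profiling with expression-matched background selection,
    reactivity-constrained secondary-structure context summaries behind a
    pluggable folding engine, targeted bisulfite-sequencing deletion-rate
    quantification, and a synthetic RT-stop library generator that plants
    ground-truth sites so every stage is testable end to end.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml,
    Biostrings
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
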