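Package: seasonet
Title: Season-Specific Co-Expression Networks from Developmental Expression Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening differentially expressed genes in short
    developmental expression time series with a deterministic mean/variability
    threshold rule, building per-condition Pearson co-expression networks at a
    fixed |PCC| cutoff, comparing networks across growth conditions (shared,
    unique and sign-flipped gene pairs), extracting transcription-factor-target
    regulatory networks and ranking hub regulators, and confirming TF-target
    edges by scanning promoter regions upstream of the translation start site
    for IUPAC cis-regulatory elements. Includes a seeded synthetic-data
    generator that emulates a two-season, multi-tissue sampling design with a
    precipitation-driven hub regulator, season-dependent correlation sign
    flips, leaf-expressed decoy genes and a mini-genome with planted promoter
    elements, so the whole pipeline can be validated against known ground
    truth.
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
    igraph,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
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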