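Package: lipidpipe
Title: Quantitative Tissue Lipidomics from Class-Separation MS Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for species-level quantification of
    tissue lipidomes from exported MS feature tables: lipid shorthand parsing
    with elemental compositions and adduct m/z values, isotopologue envelopes
    with type I and type II isotopic correction, one-point internal-standard
    calibration to nmol per mg wet tissue, three-step QC curation (blank,
    robustness, prevalence) with group-wise imputation, lysophospholipid
    hydrolysis-ratio stability statistics (Dunnett, Welch, volcano, PCA), and
    liquid-liquid fractionation summaries (Tukey with compact letter
    displays). A seeded synthetic-lipidome generator renders ground-truth
    feature tables so every pipeline stage is verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    stats,
    utils,
    multcomp,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
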