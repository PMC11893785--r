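Package: fgf14gaa
Title: Long-Read Genotyping of the FGF14 Intron-1 GAA Repeat Locus
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Sizing and configuration analysis of the GAA tandem-repeat
    expansion in intron 1 of FGF14 (the SCA27B locus) from long reads.
    Extracts locus-spanning reads by flanking anchor sequences, decomposes
    repeat tracts into the six canonical motifs (waterfall decomposition),
    sizes alleles from the distance between flank/repeat junction 20-mers,
    clusters reads into diploid allele calls, classifies repeat
    configurations and penetrance bands, predicts repeat-primed PCR
    outcomes, genotypes the upstream rs534066520-like SNP, and aggregates
    cohort frequency tables with exact tests. Includes a deterministic
    synthetic-read generator (HiFi-like error model, gel size selection)
    so the whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
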