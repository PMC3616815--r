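Package: isoprime
Title: Gene-Specific qPCR Assay Design and Quantification for Paralogous
    Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building quantitative RT-PCR assays that discriminate
    individual members of closely related multigene families. Classifies
    alignment polymorphisms into gene-differentiating and
    allele-differentiating SNPs, designs gene-specific primer pairs under
    3'-anchoring and physicochemical constraints, screens specificity by
    mismatch-aware in-silico PCR and melt-curve quality control, and
    quantifies expression by the standard-curve method with
    efficiency correction and reference-gene normalization. Includes
    neighbour-joining phenetics for subfamily structure and a synthetic-data
    generator for paralog families and qPCR runs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
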