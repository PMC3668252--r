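Package: hybridID
Title: Molecular Diagnosis of Natural Hybrids from Diagnostic Sequence Differences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for identifying natural interspecific
    hybrids from per-locus sequence alignments of two parental species and
    putative hybrids. Finds fixed diagnostic differences between species
    (substitutions and indel events treated as single characters), scores
    chromatogram additivity of IUPAC-coded direct-sequencing consensus reads,
    resolves diploid genotypes into haplotype pairs with an
    expectation-maximisation frequency model plus panel-constrained phasing,
    builds median-joining haplotype networks, classifies hybrid generation
    (F1, F2, backcross) under a Mendelian multilocus model, assigns the
    maternal parent from uniparentally inherited chloroplast sequence, and
    compares spore germination rates. Includes a synthetic-data generator
    that emulates a two-species hybrid-zone study design end to end, with
    truth tables for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
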