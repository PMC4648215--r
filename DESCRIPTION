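Package: tcrep
Title: T-Cell Receptor Repertoire Diversity, Overlap and Cohort Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of T-cell receptor (TCR) CDR3 clonotype tables from
    skin biopsy cohorts: reading and writing immunoSEQ-export and AIRR
    rearrangement TSV dialects, Shannon-entropy based clonality and
    richness summaries, V/J gene-segment usage, pairwise repertoire
    overlap with group pooling, paired-tissue clone comparison,
    cross-patient public-clone detection, and group-level inference
    (unpaired t-tests and one-way ANOVA with SEM error bars). Includes a
    seeded synthetic cohort generator that emulates the statistical
    structure of a three-group psoriasis skin study (normal,
    non-lesional, lesional) so the whole pipeline is testable without
    access to deposited sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    stats,
    tools,
    utils,
    jsonlite,
    withr,
    generics,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
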