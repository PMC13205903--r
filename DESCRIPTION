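Package: successr
Title: Microbial Succession, Transmission and Community Assembly Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal microbiome studies spanning maternal,
    juvenile and adult stages: compositional diversity (CLR, Aitchison
    distance, PCoA, PERMANOVA, alpha diversity), beta-diversity partitioning
    into turnover and nestedness with permutation tests, Levins niche breadth,
    prevalence-based differential feature calling, colonization-pattern
    classification and developmental-trajectory comparison, EM-based microbial
    source tracking with replicated contrasts, strain-sharing calls from
    normalized phylogenetic distances, betaNTI / Raup-Crick (Bray-Curtis)
    assembly-process classification, and Sloan neutral community model
    fitting. Includes synthetic-data generators with known ground truth for
    parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    jsonlite,
    optparse,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
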