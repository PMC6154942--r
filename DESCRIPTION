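Package: gutmets
Title: Gut Microbiota Dysbiosis, Metabolic Syndrome and Economic Status
    Analysis Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of a population-scale gut microbiome
    association pipeline for metabolic syndrome (MetS) cohorts: synthetic
    cohort and OTU-table simulation with planted ground-truth effects,
    rarefaction and alpha/beta diversity (Shannon, Faith's phylogenetic
    diversity, Bray-Curtis), PERMANOVA with a subsample significance
    saturation procedure, confounder-adjusted per-OTU linear association
    modelling with Benjamini-Hochberg false discovery rate control,
    directional taxon network summaries, a weighted microbial MetS index,
    and additive lifestyle-dysbiosis risk stratification.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    picante,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
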