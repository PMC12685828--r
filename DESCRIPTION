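Package: micronet
Title: Diversity, Differential Abundance and Co-Occurrence Network Stability
    for Intercropping Soil Microbiomes
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-style toolkit for the downstream analysis of
    amplicon (ASV) count tables from cropping-system experiments: alpha
    diversity (Shannon, Gini-Simpson, Chao1), Bray-Curtis beta diversity with
    principal coordinates analysis and permutation PERMANOVA, LEfSe-style
    biomarker discovery (Kruskal-Wallis screen plus a bootstrapped linear
    discriminant effect size), signed co-occurrence network construction with
    composite complexity, robustness under random taxon removal and
    efficiency-based vulnerability, distance-based redundancy analysis
    against soil covariates, and two-factor block ANOVA summaries of soil
    properties with LSD compact letter displays. A Dirichlet-multinomial
    community simulator with planted diversity shifts, correlation modules
    and soil-covariate links provides ground truth for recovery testing of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
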