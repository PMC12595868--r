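Package: perenniome
Title: Rhizomicrobiome Stability, Core Membership and Recruitment Analysis
    for Perennial Grain Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing rhizosphere and root-endosphere bacterial
    communities between perennial and annual crops from 16S rRNA amplicon
    sequence variant (ASV) tables. Implements counts-per-thousand
    normalization with sparsity and abundance filtering, alpha diversity,
    Bray-Curtis dissimilarity with PERMANOVA, mean pairwise dissimilarity
    (mu_D) homogeneity comparisons, an inter-annual relative-abundance
    stability index (delta-RA), abundance-occupancy core-microbiome
    detection, indicator species analysis (IndVal) with a permutation null,
    paired rhizosphere-to-endosphere recruitment quantification, and
    environment-wide association of ASVs against a sequence-indexed
    indicator database. A synthetic-data generator emulating a multi-site,
    multi-year, two-depth, two-crop factorial design provides ground truth
    for every stage.
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
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    biomformat,
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
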