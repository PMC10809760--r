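Package: hadalguilds
Title: Respiratory Guild Succession and Decay Kinetics in Hadal Sediment Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of metagenome-assembled genomes (MAGs) from
    deep-sea sediment cores: rule-based classification of respiratory guilds
    (aerobic, nitrogen, sulfur, metal respiration, putative fermenters) from
    gene content and KEGG-style module completeness, carbohydrate-active
    enzyme (CAZyme) secretion strata, redox-zone assignment of core horizons,
    abundance-weighted functional depth profiles, exponential decay and growth
    kinetics (half-lives and doubling times) under a sedimentation-rate age
    model, and an ordination and statistics layer (Bray-Curtis PCoA, Hellinger
    PCA, PERMANOVA with FDR, Welch's t, Ward clustering). Ships a synthetic
    community simulator with planted ground truth so the full pipeline is
    testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape
Config/testthat/edition: 3
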