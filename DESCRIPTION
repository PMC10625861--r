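Package: zoopvert
Title: Depth-Stratified Zooplankton Metabarcoding Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for depth-stratified zooplankton metabarcoding
    surveys sampled with paired day/night MOCNESS tows. Computes per-taxon
    vertical statistics (relative-abundance-weighted mean depth of occurrence,
    epipelagic/mesopelagic habitat classification), detects diel vertical
    migration from day/night read-depth shifts with a four-criterion rule,
    estimates per-taxon environmental ranges (temperature, dissolved oxygen,
    chlorophyll-a) from 1-m binned CTD profiles, tabulates province occupancy
    and endemism, and runs the community and trait-based statistical contrasts
    (Bray-Curtis/Jaccard beta-dispersion, nMDS, Kruskal-Wallis with Dunn's
    post-hoc, ties-corrected Spearman, chi-square). Includes a seeded
    synthetic-survey generator with planted vertical distributions, migration
    behaviour, province occupancy, traits and environmental gradients so every
    stage can be validated against ground truth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
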