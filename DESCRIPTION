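Package: ammsens
Title: Meta-Analysis of Plant Ammonium Sensitivity from Biomass Response Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to classify plant species by their sensitivity to ammonium
    nutrition from study-level biomass data. Computes the natural-log biomass
    response ratio (LnBR) of ammonium- versus nitrate-fed plants with its
    large-sample variance, aggregates organ biomasses under an independence
    assumption, pools effects per species or cultivar with a
    DerSimonian-Laird random-effects model (study-level bootstrap confidence
    intervals, heterogeneity Q, Rosenthal fail-safe N), stratifies by
    hydroponic solution pH, relates pooled effects to Ellenberg indicator
    values and nitrogen-transporter gene counts by linear regression and PCA,
    and computes 15N tracer uptake and root-to-shoot translocation
    partitions. A seeded synthetic-data generator emulates the study tables,
    trait tables and labeling time courses so every stage is testable with
    known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
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
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
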