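Package: cycadcpi
Title: Conservation Prioritization Index for Veracruz Cycads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a composite Conservation Prioritization Index (CPI) for
    cycad species from mixed categorical and numeric risk attributes, and
    carries the downstream prioritization analysis: min-max standardization
    and inversion of risk variables, Pearson correlation screening, Multiple
    Factor Analysis of mixed data, Gower-distance Ward clustering with
    multiscale-bootstrap approximately-unbiased (AU) cluster support, gamma
    log-link GLM geographic trend models with explained deviance, and
    geospatial range metrics (convex-hull extent of occurrence, IUCN
    Criterion B preliminary categories, protected-area overlays,
    canopy-height habitat-loss fractions, 1-km2 richness rasters and
    protected-area gap summaries). Includes a seeded synthetic-data
    generator emulating the structure of the Veracruz cycad study system so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    cluster,
    geosphere,
    mgcv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
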