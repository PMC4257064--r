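Package: deforisk
Title: Deforestation Risk Mapping, Rate Projection and Carbon Accounting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for regional deforestation-risk analysis:
    consensus forest-change maps from multiple classifiers, annualized
    deforestation rates (Puyravaud and FAO forms) with business-as-usual area
    projection, a friction-based least-cost travel-time accessibility index,
    a from-scratch presence-only maximum-entropy (Maxent-style) risk model
    with replicate AUC assessment and permutation variable contributions,
    rate-constrained hard risk classification, carbon and CO2 emissions
    accounting, and Mann-Whitney validation of predicted risk against later
    observed change. Includes a seed-reproducible synthetic landscape
    generator so the whole pipeline can be exercised and tested without
    external raster data, plus lightweight planar raster I/O (ESRI ASCII grid
    and single-band float32 GeoTIFF).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
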