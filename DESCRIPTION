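Package: phenoheight
Title: Plot-Level Plant Height Phenotyping from UAV Crop Surface Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-validated pipeline for extracting plot-level plant
    height from UAV-derived elevation rasters in wheat breeding trials.
    Computes crop surface models (DSM minus DTM), reduces them to per-plot
    heights via buffered regions of interest and a percentile statistic,
    assesses georeferencing accuracy against surveyed ground targets, and
    estimates genotypic values, variance components and heritabilities for
    alpha-lattice designs by REML, including pedigree-based additive
    relationship matrices and genotype-by-year models. Includes a field-trial
    simulator (terrain, canopy surfaces, layouts, ground measurements,
    targets, pedigrees) with known ground truth, plus minimal GeoTIFF and
    GeoJSON readers and writers so no external geospatial stack is required.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
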