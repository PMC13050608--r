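Package: scPopViz
Title: Scalable Cell Population Plots for Single-Cell Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds sample-by-cell-type population matrices from per-cell
    annotations, applies a reproducible view-transform algebra
    (normalization, log transform, metadata sorting and filtering,
    grouping, cell-ontology hierarchy collapse, transposition), and
    renders a deterministic composite figure -- a central heatmap with
    expandable bar-chart rows and aligned bar, stacked-bar, and violin
    side panels -- to SVG or PNG. Includes a traditional stacked-bar
    preset, AnnData (h5ad and zarr) observation-table ingestion, a
    seed-reproducible synthetic atlas generator with ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    S4Vectors,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
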