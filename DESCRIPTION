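Package: dvvrisk
Title: Climate-Based Spatial Risk Modelling of Western Corn Rootworm Spread in Europe
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Thermal-envelope suitability, logistic spread projection and
    centroid-based country risk classification for the western corn rootworm
    (Diabrotica virgifera virgifera) in Europe. Generates synthetic gridded
    monthly temperatures emulating E-OBS structure, computes temperature
    anomalies against a 1991-2020 reference, growing degree days and
    threshold/persistence suitability masks for the beetle and for maize,
    simulates constrained cellular spread driven by a logistic growth target,
    and classifies country centroids into low/medium/high risk per horizon
    with circular buffer-zone output. Rasters are exchanged as Esri ASCII
    grids, vector layers as GeoJSON, tables as CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
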