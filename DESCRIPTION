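Package: somexposure
Title: Supervised Self-Organizing Maps for Air-Pollution Exposure and Binary Health Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Kohonen self-organizing maps (SOM), unsupervised and supervised
    (two-layer XY variant), for classifying binary health outcomes from
    multidimensional environmental-exposure and demographic data. Includes a
    seeded synthetic study generator (monitoring-station pollutant fields,
    right-skewed patient cohort, logistic outcome model), inverse-distance
    weighted interpolation of station measurements to patient coordinates with
    lagged exposure assembly, chained-equation imputation and feature coding,
    Ward clustering of codebook vectors, U-matrix and code-plot summaries, and
    map-quality metrics (quantization and topographic error, per-node quality,
    confusion metrics).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
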