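Package: lvrscape
Title: Landscape-Scale Analysis of Lumber Value Recovery in Northern Hardwoods
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for studying landscape-scale variation in lumber value
    recovery (LVR) of northern hardwoods (yellow birch, sugar maple). Implements
    a recalibrated lumber-value scoring model (quality index and sawn-wood yield
    as functions of per-grade log volumes), stand-level feature construction
    (eligibility filtering, exponential Shannon diversity indices, critical
    acid-load variables, plot-level LVR aggregation), stochastic gradient
    boosted regression tree models of plot LVR with grid tuning, relative
    influence, partial dependence and model simplification, and fixed
    distance-band spatial hotspot detection (Global Moran's I band selection,
    Getis-Ord Gi*, five-level cluster classification, GeoJSON output). Includes
    synthetic-data generators (a sawing study and a spatial plot network with
    planted clusters) so every stage is testable without confidential inventory
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
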