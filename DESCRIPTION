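Package: defoliascan
Title: Early Detection of Defoliator Damage from Canopy Spectra and LiDAR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Individual-tree early detection of defoliating-pest damage in
    conifer stands from paired UAV hyperspectral canopy reflectance and
    LiDAR point clouds. Implements instability-index (ISIC) band screening
    with adjacent-difference threshold tuning, the successive projections
    algorithm (SPA), and the chained ISIC-SPA selector; narrowband
    vegetation-index construction with exhaustive Spearman-correlation
    search; per-tree LiDAR height and intensity metrics; Kruskal-Wallis
    feature screening with a mild-versus-moderate early-detection
    criterion; and random-forest classification of mild, moderate and
    severe damage stages with confusion-matrix accuracy metrics and
    permutation importance. A synthetic-data generator emulates the
    spectral and structural signatures of progressive defoliation so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
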