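Package: facemark
Title: Ensemble-Based Automatic Landmarking of 3D Facial Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic anatomical landmarking of 3D facial surface scans with
    minimal training data. Facial meshes are flattened by an ellipsoid fit and
    Mercator projection into aligned texture, heightmap and curvature rasters,
    from which a 15-channel feature bank is built. A family of Gabor-jet
    template ("bunch graph") base landmarkers, including a global search
    guided by principal components of training landmark configurations, is
    combined by bagging or stacked regression. Includes leave-one-out accuracy
    evaluation, a synthetic face and twin-cohort generator for end-to-end
    testing, and twin-based narrow-sense heritability estimation of geometric
    facial features with importance maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    optparse,
    png,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    vegan
Config/testthat/edition: 3
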