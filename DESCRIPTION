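Package: nutrigeom
Title: Curvature, Surface Area and Distance Between Nutritional
    Performance Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential-geometric characterization of performance
    landscapes from geometric-framework (GF) nutrition experiments.
    Fits quadratic response surfaces of a performance trait over
    protein and carbohydrate intakes, computes Gauss and mean
    curvature fields via the first and second fundamental forms of the
    Monge patch, measures landscape 'wiggliness' as the ratio of the
    landscape's surface area to that of a flat landscape over the same
    domain, and compares landscapes as three-dimensional point sets
    with the Hausdorff distance, including bootstrap confidence
    intervals. Ships canonical validation surfaces (flat, saddle,
    sphere, cylinder) and a simulator for rail-and-dilution GF
    designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    boot,
    jsonlite,
    mgcv,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
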