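Package: facedev
Title: Deviation Analysis of Paired Facial Surface Meshes
Version: 0.1.0
Authors@R: person("Facedev", "Maintainers", email = "facedev@example.org",
    role = c("aut", "cre"))
Description: Quantifies the geometric agreement between a reference facial
    surface shell (such as one segmented from cone beam computed tomography)
    and a lower-resolution depth-sensor face scan. Provides STL and PLY mesh
    input/output, landmark-seeded rigid superimposition refined by trimmed
    iterative closest point restricted to expression-stable facial regions,
    per-vertex absolute surface-deviation maps with a 3 mm clinical-relevance
    threshold over a named facial-region atlas, a synthetic paired-face
    generator with known ground truth for validation, and cohort-level
    contingency (Fisher's exact) and rank-based (Friedman) statistics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
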