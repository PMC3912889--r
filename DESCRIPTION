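Package: dentalign
Title: Two-Phase Rigid Registration of Multi-Resolution Dental Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Rigid registration of triangle-surface meshes that differ in
    resolution and coverage, such as a crown-only intraoral scan against a
    full crown-and-root cone-beam CT reconstruction. Provides STL
    input/output with vertex welding, discrete Gaussian curvature by the
    angle-deficit formula, curvature-thresholded feature extraction, a
    constraint-based three-point coarse alignment, and iterative
    closest-point refinement with singular-value-decomposition transform
    updates. A synthetic phantom generator produces mesh pairs with known
    ground-truth transforms so every stage can be validated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RANN,
    generics,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
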