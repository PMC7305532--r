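Package: archforce
Title: Orthodontic Force Prediction for Second Sequential Loop Archwires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the unidirectional (occlusal-gingival) orthodontic force
    delivered by a second sequential loop archwire. Models the archwire segment
    between the two anchorage teeth as a simply supported Euler-Bernoulli beam
    loaded at the bracket of the target tooth, parses the clinical archwire
    naming code (material, cross-section, anchorage distance, offset distance),
    calibrates empirical correction factors against measured load-deflection
    tables by ordinary least squares, composes them with base normalization at a
    reference archwire, and validates corrected predictions by per-archwire mean
    relative error. Includes the published 10x10 measurement table as a fixture
    and a synthetic-table generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
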