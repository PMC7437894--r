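Package: bronchoquant
Title: Integral-Based Airway Wall Morphometry on CT Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative airway morphometry on single axial CT slices.
    Implements radial density-profile casting, full-width-at-half-maximum
    and integral-based localization of the inner and outer airway wall
    border, contour completion near adjacent vessels by least-squares
    ellipse fitting (standard method) or a median-attenuation threshold
    rule (modified method), and the four airway metrics: total diameter,
    lumen area, wall area and wall thickness. Includes a synthetic CT
    phantom generator with analytic ground truth for validating the
    methods and for studying the measurement bias introduced by
    contrast-enhanced vessels in contact with the airway wall.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
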