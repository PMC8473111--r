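Package: isomspr
Title: Sitting-Posture Recognition from Seat-Pressure Maps with an Improved Self-Organizing Map
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies sitting postures from 32x32 seat-pressure frames using
    per-frame principal-component reduction and a six-node self-organizing map
    on a hexagonal lattice, trained by competitive learning with a Gaussian
    neighborhood and exponentially decaying schedules. Includes the
    improved-SOM step that scores each training sample's differentiation
    between its best-matching node and the strongest adjacent rival, removes
    poorly differentiated samples, and retrains. Ships a seeded synthetic
    pressure-map generator emulating six posture classes, the resistive sensor
    transfer functions, one-vs-rest confusion-matrix metrics, and an
    end-to-end reproducible experiment driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
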