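Package: filmdose
Title: Radiochromic Film Dosimetry Quality Assurance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quality-assurance workflow for radiochromic film
    dosimetry in radiotherapy: reading flatbed-scanner TIFF images and DICOM
    RT Dose exports, uncertainty-weighted calibration of rational and
    polynomial dose-response models, single-channel and multichannel
    (disturbance-separating) dose reconstruction, automatic film-to-plan
    registration by normalized cross-correlation with a small-angle sweep,
    and gamma-index comparison with configurable distance-to-agreement and
    dose-difference criteria. Includes a synthetic scan generator so the
    whole pipeline is testable without physical films.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tiff,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
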