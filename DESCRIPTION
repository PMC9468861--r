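Package: octatten
Title: Attenuation-Based Grading of Brain-Tumor Infiltration from OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for grading brain-tumor infiltration from
    optical coherence tomography (OCT) intensity images. Implements a
    single-scattering signal model with system corrections (spectrometer
    roll-off, confocal collection efficiency, refraction-shifted focus and
    refractive-index depth rescaling), log-linear estimation of the
    attenuation coefficient and backscattered intensity from averaged
    B-scan patches, mirror-sweep calibration of the roll-off and confocal
    models, per-label summary statistics with a between-system
    relative-difference comparison, and a four-stage tumor/healthy
    classification protocol (optical-feature and image-patch networks)
    evaluated by leave-one-patient-out cross-validation. Includes a seeded
    synthetic-cohort generator built on the same forward model for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    minpack.lm,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
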