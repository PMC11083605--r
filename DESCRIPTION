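Package: boluscope
Title: Bolus Homogeneity Imaging and Masticator Transposition for Oral
    Processing Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipeline for comparing in vivo and in vitro
    mastication of soft foods. Provides CIELAB colour-difference
    computation, region-of-interest extraction and red-channel variance
    homogeneity scoring on surface-coloured bolus photographs, hardness
    extraction from penetration and back-extrusion force curves,
    per-subject masticatory parameter derivation, transposition of in
    vivo parameters to a chewing-simulator (masticator) operating grid,
    nearest-value matching of in vitro settings to in vivo bolus
    measurements, mixed-design ANOVA and triangle-test inference, and
    synthetic-data generators for panels, two-phase mixing images and
    force curves.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
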