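Package: eipdt
Title: Error Inflection Point-Discriminant Technique for Pollen Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects Human Influence Index (HII) thresholds that separate
    native, secondary, and artificial vegetation systems from the
    cross-validated errors of pollen-climate transfer functions; classifies
    modern and fossil pollen spectra as native or human-affected with linear
    discriminant analysis; and reconstructs past mean annual temperature and
    precipitation from native-vegetation calibration sets only. Provides
    weighted-averaging partial least squares (WA-PLS) and modern-analogue
    transfer functions with leave-one-out validation, probit-scale cumulative
    error curves over HII, continuous piecewise-linear (segmented) breakpoint
    detection with bootstrap uncertainty, and a synthetic-data generator with
    planted disturbance thresholds so the whole pipeline can be validated by
    parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
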