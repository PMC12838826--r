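Package: sonodent
Title: Ultrasonic Indentation Simulation and Tissue Stiffness Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates A-mode pulse-echo ultrasound signals from elastic
    tissue phantoms compressed by a cylindrical indenter, estimates
    time-of-flight (ToF) differences between baseline and loaded signals
    with sub-sample precision (envelope-peak tracking and windowed
    normalized cross-correlation), and inverts them to tissue stiffness
    through a flat-punch Hertzian contact model. Includes calibration fits
    of ToF difference against load and Shore hardness, sensitivity analysis
    for operating-pressure selection, stiff-inclusion (lesion) screening
    with repeated-measurement statistics, and a reproducible end-to-end
    experiment pipeline with a command-line entry point.
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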