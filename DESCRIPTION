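Package: aaapiv
Title: Pulsatile Hemodynamics and LED-PIV Analysis for Compliant Aneurysm Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale analysis pipeline for particle image velocimetry (PIV)
    studies of pulsatile flow in compliant abdominal aortic aneurysm (AAA)
    phantoms driven by a hybrid mock circulatory loop. Provides an idealized
    axisymmetric aneurysm geometry, Womersley pulsatile flow solutions, a
    discrete-time simulator of the loop (three-element Windkessel setpoint law,
    PID-regulated pressure chamber, compliant segment, multi-kHz sensor
    logging), a synthetic double-exposure particle-image generator with ground
    truth, a multi-pass FFT cross-correlation PIV engine with window
    deformation and three-criterion vector validation, and derived hemodynamic
    metrics (phase statistics, velocity-fluctuation RMS, vorticity,
    axisymmetric flow-rate integration, wall deformation, pressure-strain
    elastic modulus).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    signal,
    stats,
    tiff,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
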