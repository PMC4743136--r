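Package: rbscreen
Title: Signal Processing and Decision Core of a Retinal Birefringence
    Scanning Vision Screener
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyzes the four-channel signals of a retinal
    birefringence scanning (RBS) pediatric vision screener. Provides a
    Stokes/Mueller polarization model of the double-pass scanning
    polarimeter (spinning half-wave plate, cornea, radially birefringent
    Henle fiber layer), a synthetic record generator with scan-synchronous
    background, power-line interference and defocus-dependent
    center/annulus energy split, phase-shift-subtraction (PhSS) noise
    cancellation, synchronized-sampling half-harmonic power spectra,
    calibration and application of central-fixation criteria (optimized
    scalar threshold and linear discriminants), the normalized (C-A)/(C+A)
    goodness-of-focus statistic with focus-curve generation, and
    session/study level screening decisions with sensitivity/specificity
    accounting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
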