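Package: veinppg
Title: Retinal Vein Photoplethysmography and Non-Invasive Intracranial
    Pressure Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates intracranial pressure (ICP) from retinal vein
    photoplethysmography (PPG). Fits a cardiac-locked two-harmonic model
    to green-channel fundus video to map vein pulse amplitude, extracts
    the maximum hemivein amplitude per induced intraocular pressure (IOP)
    step under ophthalmodynamometry, detects the rising phase of the
    amplitude-versus-IOP curve by exhaustive consecutive-window regression
    with correlation, slope and amplitude filters, and extrapolates the
    best rising segment to zero amplitude: the x-intercept estimates ICP.
    Includes posture conversion, subject-level averaging, Bland-Altman
    method-agreement statistics with limits-of-agreement sample-size
    computation, and a synthetic phantom module (amplitude curves and
    fundus video with known ground-truth ICP) so the whole chain is
    verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
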