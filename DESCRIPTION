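Package: archpwv
Title: Aortic Pulse Wave Velocity from Mock-Circulatory-Loop Acquisitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for ex vivo aortic pulse wave
    velocity (PWV) experiments on a mock circulatory loop. Provides a
    synthetic bench-rig generator (half-sine ventricular ejection into a
    three-element Windkessel, Moens-Korteweg wall mechanics, Type I versus
    Type III aortic arch configurations, stent-graft stiffening), a
    cross-correlation transit-time estimator with sub-sample refinement,
    pixel-calibrated centerline arc-length measurement with a
    pressure-length regression, hemodynamic derivations (pulse pressure,
    mean arterial pressure, PWV, stent-graft oversizing and eligibility),
    and the paired statistical layer (normality-routed paired comparisons,
    ICC(A,1) reliability, and paired-t sample-size calculation).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
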