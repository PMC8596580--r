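Package: sipmct
Title: Response Modelling of SiPM-Based Scintillation Detectors for Photon-Counting CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the pulse-height response of silicon-photomultiplier (SiPM)
    scintillation detector pixels for photon-counting computed tomography.
    Implements the analytic saturation model with optical crosstalk (Borel and
    generalized Poisson trigger statistics, the per-SPAD partial-pulse
    recursion, and the iterative crosstalk correction), a Monte Carlo
    pulse-shape simulator, photopeak spectroscopy with resolution correction
    through a monotone response lookup curve, pulse-duration and count-rate
    metrics, and dark-pulse calibration of SiPM parameters. Ships published
    parameter sets for LuAP:Ce, LYSO:Ce and LaBr3:Ce scintillators and
    NUV-HD SiPMs, plus design-study sweep utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, grDevices, utils, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
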