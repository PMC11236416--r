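Package: emdtrack
Title: Tracking Spike-Sorted Units Across Sessions with the Earth Mover's Distance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking single units across chronic high-density
    extracellular recording sessions. Units sorted independently per session
    (phy/Kilosort convention) are localized in 3D from peak-to-peak waveform
    amplitudes with a 1/R monopole model, matched between sessions by solving
    an exact earth mover's distance (partial assignment) problem over a
    combined physical-plus-waveform distance, corrected for rigid vertical
    drift via the kernel-density mode of matched z-displacements, and
    filtered with a z-distance threshold calibrated by fitting a folded
    Gaussian plus exponential mixture to the z-distance distribution.
    Includes chain tracing across many sessions, visual-response reference
    validation (PSTH and visual-fingerprint correlations), and a synthetic
    drifting-population simulator with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
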