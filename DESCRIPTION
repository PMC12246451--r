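Package: ptychodesign
Title: Experiment Design for 4D-STEM Electron Ptychography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans 4D scanning transmission electron microscopy (4D-STEM)
    ptychography acquisitions. Given microscope, scan and detector parameters
    the package derives every sampling, resolution, probe-window, defocus and
    dose quantity needed to judge an acquisition plan, evaluates the built-in
    feasibility checks for direct single-side-band (SSB) and iterative (ePIE)
    reconstruction methods, and tabulates a camera-length selection guide.
    The analytic SSB phase contrast transfer function is computed from
    double-disk-overlap geometry. A synthetic weak-phase 4D-STEM simulator
    with reference SSB and ePIE reconstructions validates the sampling and
    transfer-function predictions end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
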