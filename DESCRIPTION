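Package: scfs
Title: Single-Cell Force Spectroscopy Simulation and Rupture-Force Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for AFM-based single-cell force spectroscopy
    (SCFS) retract curves: baseline and contact-point correction, step
    detection, classification of abrupt force drops into bond-rupture jumps
    versus membrane-tether detachments, rupture-force quantification, pooling
    into condition datasets, quartile summaries, pulling-velocity series and
    exact/approximate Wilcoxon rank-sum comparisons. Includes a physics-based
    synthetic force-curve generator (Bell-Evans bond rupture under ramp
    loading, constant-force membrane tethers, Gaussian deflection noise,
    baseline drift) with condition presets for fibroblast and epithelial
    cell-cell pairings and drug treatments, plus thermal-noise records and
    thermal-tune spring-constant calibration (equipartition and
    simple-harmonic-oscillator spectral fit), so that every pipeline stage is
    testable against generated ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    RcppTOML,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
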