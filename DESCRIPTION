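Package: hyperkin
Title: Simulation and Kinetic Analysis of Ratiometric Hydrogen Peroxide
    Biosensor Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying intracellular hydrogen peroxide dynamics
    and cellular disulfide-reduction (antioxidant) capacity from
    dual-excitation ratiometric biosensor recordings such as HyPer. Provides
    a mechanistic forward simulator of single-cell 420/490 nm fluorescence
    time series under oxidant pulse protocols, compartment presets (cytosol,
    mitochondrion, endoplasmic reticulum), intracellular pH clamping, and
    pharmacological perturbations of the thiol-reduction machinery; an
    analysis chain covering ratio computation, baseline estimation,
    dynamic-range normalization, protocol phase segmentation and
    three-parameter exponential recovery fits; cohort-level statistics
    including group comparisons and the correlation of biosensor recovery
    rate with cell migration efficiency; and a config-driven pipeline with
    plain-text input/output formats.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
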