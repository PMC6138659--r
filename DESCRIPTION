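Package: netphases
Title: Quantitative Phase Analysis of NETosis from Time-Lapse Microscopy
    and Atomic Force Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the single-cell biophysical analysis of neutrophil
    extracellular trap formation (NETosis). Segments chromatin-stained
    time-lapse movies into projected area-time traces, detects the three
    phases of NETosis (activation, chromatin expansion, NET release) and
    their characteristic time points, fits effective diffusion constants to
    the chromatin expansion, computes the entropic chromatin swelling
    pressure from a coarse-grained polymer-network model, estimates the
    Arrhenius activation energy of the activation phase, analyses atomic
    force microscopy force curves (pyramidal-tip Hertz elasticity, membrane
    tether tensions, constant-height swelling pressure), and quantifies
    membrane rupture geometry (velocity fields, ellipse fits, rupture-axis
    retraction speeds). A synthetic-data module generates calibrated movies,
    cohorts and force curves with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    MASS,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
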