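Package: tqdf
Title: Triple-Colour Quantitative Dynamic Footprinting of Integrin
    Activation on Rolling Neutrophils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for triple-colour quantitative dynamic
    footprinting (TqDF) microscopy of beta2-integrin conformations on
    rolling neutrophils.  Converts membrane-dye TIRF intensity to
    nanometre height maps via the exponential evanescent-field decay,
    segments the cell footprint and reporter-antibody clusters, classifies
    clusters into extension/headpiece conformational states, tracks cells
    (rolling velocity, arrest) and clusters (state-transition history,
    lifetimes), localizes clusters on membrane hills and valleys and
    within ligand reach of the substrate, quantifies antibody-binding
    sites from bead calibration curves, and computes FRET efficiencies,
    spectral overlap integrals, Forster radii and donor-acceptor
    distances.  A synthetic-scene generator with full ground truth stands
    in for primary-cell imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
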