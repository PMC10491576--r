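Package: chemowave
Title: Chemotactic Cell Invasion Waves in Heterogeneous Chemoattractant Fields
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analytical approximations and numerical reference solutions for
    one-dimensional chemotactic cell invasion waves driven by heterogeneous,
    time-varying chemoattractant fields. Provides characteristic maps and
    moving-front trajectories for linear and separable chemotactic flux
    fields, outer (small-diffusion) cell density formulas, uniformly valid
    composite solutions with an erf transition layer, asymptotic solutions of
    the oscillatory plateau equation, reductions of a microfluidic
    cell-culture model (weak consumption, high-nutrient and low-nutrient
    scenarios with Michaelis-Menten or Hill uptake), and a conservative
    finite-volume solver for the full advection-diffusion-growth model that
    serves as the validation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
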