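Package: reactoscope
Title: Event-Driven Reactive Microscopy Simulation and Single-Cell Control
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hardware-free framework for designing and testing reactive
    microscopy experiments. An event engine (triggers and effects) drives a
    simulated microscope imaging a growing, dividing cell population with
    light-inducible gene expression, decaying dye signal and targeted DMD
    illumination with bleed-through. On top of the simulator the package
    implements adaptive exposure control, Kalman and finite-state-projection
    Bayesian filtering of gene-expression states, receding-horizon model
    predictive control of expression at the population and single-cell
    level, and single-cell optogenetic targeting strategies (ring regions,
    islet selection) with endpoint recombination phenotyping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'rng.R'
    'logging.R'
    'expression.R'
    'population.R'
    'microscope.R'
    'segmentation.R'
    'tracking.R'
    'kalman.R'
    'fsp.R'
    'fitting.R'
    'control.R'
    'events.R'
    'targeting.R'
    'config.R'
    'outputs.R'
    'scenarios.R'
    'reactoscope-package.R'
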