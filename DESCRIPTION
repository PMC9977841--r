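Package: tsgeom
Title: Transition-State Geometry Prediction from Reactant and Product Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts transition-state (TS) interatomic distances of single-step
    gas-phase reactions from atom-mapped reactant, product, and linearly
    interpolated structures using a pair-sequence-interaction neural network,
    reconstructs 3D TS geometries by weighted nonlinear optimization under
    Euclidean distance-matrix constraints, and explores multiple reaction paths
    via normal-mode sampling and affinity-propagation clustering. Includes
    multi-frame XYZ input/output, test-time augmentation by reaction reversal,
    checkpoint ensembling, bond-change error stratification, and a synthetic
    reaction generator with exactly realizable ground-truth TS geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
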