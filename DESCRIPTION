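Package: fminspect
Title: Detection and Identification of Foreign Matter in Transfusion-Bottle Image Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated visual inspection of liquid pharmaceutical
    containers imaged with a spin-stop mechanism. Implements per-pixel
    Gaussian-mixture background modeling to extract moving objects from
    grayscale frame sequences, connected-component blob analysis with a
    fifteen-feature gray-statistics and Hu-moment descriptor set, multi-class
    ReliefF feature weighting, and a three-layer backpropagation neural
    network whose initial connection weights and thresholds are found by the
    Mind Evolutionary Algorithm (similartaxis within groups, dissimilation
    across groups). Includes a synthetic-scene generator that produces frame
    sequences with ground-truth masks and labeled feature datasets, an
    end-to-end qualified/unqualified verdict pipeline, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    nnet,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
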