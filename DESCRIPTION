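Package: thermogrid
Title: Human Activity Recognition from Low-Resolution 8x8 Thermal Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for unobtrusive human activity recognition with 8x8
    infrared array sensors (AMG8833-class thermopile grids). Implements
    bilinear upsampling of the 64-pixel temperature map into a body
    silhouette, a closed-form posture (standing/sitting) and motion
    (approaching/receding) detector driven by the ratio of mean frame
    temperature to ambient temperature, a deterministic synthetic
    thermal-scene simulator for generating labeled frames and
    trajectories, CSV dataset input/output with reproducible train/test
    splitting, and four classical machine-learning baselines (k-nearest
    neighbours, support vector machine, random forest, naive Bayes)
    trained on raw pixel rows. A command-line interface wires the pieces
    into end-to-end workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    class,
    e1071,
    randomForest,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
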