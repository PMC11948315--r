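Package: afcs
Title: Cyclic Activation-Function Switching for Neural Network Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training image classifiers under a cyclic
    activation-function switching (AFCS) controller: a meta-training loop that
    ranks candidate activation functions by short probe runs, trains under a
    patience rule on the validation loss, and on degradation rolls back to the
    best checkpoint, switches to the next best activation and prunes the worst
    one. Includes the patience-calibration procedure based on consecutive
    validation-loss increase counts, a runtime cost model for the extra epochs
    the controller spends, colour-range plant segmentation masks and dataset
    splitting, classification metrics, and fully synthetic desk-scale fixtures
    (blob image datasets, scripted-loss mock trainers and a tiny trainable CNN)
    so the whole controller can be exercised end to end on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    withr,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
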