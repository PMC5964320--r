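Package: boldopt
Title: Neuroadaptive Bayesian Optimization of fMRI Task Contrasts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-loop Bayesian optimization of cognitive-task selection
    for functional MRI experiments. A Gaussian-process surrogate model with
    an expected-improvement acquisition function searches a discrete task
    space to maximize a BOLD contrast between frontoparietal networks. The
    contrast is computed by an incremental general linear model on
    region-of-interest timecourses with a canonical double-gamma
    hemodynamic response function, motion confounds and linear drift.
    Includes a block-design BOLD simulator with known ground-truth
    activation surfaces, real-time-style despiking and motion scrubbing,
    group-level Gaussian-process prediction maps, linear-versus-quadratic
    mixed-model trend tests, and voxel-wise back-projection with
    max-statistic permutation inference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
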