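Package: gazeRI
Title: Relative Importance of Visual Features for Group-Level Gaze Behavior
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models group-level eye-position density maps on dynamic video
    stimuli as linear combinations of density-normalized feature maps
    (uniform, center bias, static and dynamic saliency, areas of interest).
    Per-frame eye-position densities are estimated by bivariate kernel
    density estimation with least-squares cross-validation bandwidth
    selection; feature-map weights are fitted by L1-penalized least squares
    with BIC model selection, yielding relative-importance curves over
    time. A dummy-coded interaction design extends the model to two or more
    groups, and participant-level permutation tests assess group
    differences in feature weights. A synthetic stimulus and gaze generator
    supports end-to-end validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    mgcv,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'cli.R'
    'features.R'
    'gaze-io.R'
    'gazeRI-package.R'
    'inference.R'
    'kde.R'
    'model.R'
    'synthetic.R'
    'utils.R'
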