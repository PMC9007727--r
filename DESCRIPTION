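Package: pebmeg
Title: MEG Source Reconstruction with fMRI Spatial Priors via Parametric
    Empirical Bayes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian (parametric empirical Bayes) inversion of
    the MEG inverse problem on a cortical mesh, with fMRI statistical maps
    converted into rank-one source-covariance components that act as soft
    spatial priors.  Includes a single-sphere (Sarvas) forward model for
    radial magnetometer arrays, a multiple-sparse-priors patch library,
    restricted maximum likelihood hyperparameter estimation by free-energy
    ascent, a two-dipole evoked/induced simulation study at several noise
    levels, and an evaluation battery (localization error, ROC/AUC, volume
    of interest eigenvariate time courses, time- and frequency-domain RMSE).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    pracma
Config/testthat/edition: 3
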