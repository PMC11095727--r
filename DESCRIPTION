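Package: fitscape
Title: Assessment of Uncertainty-Aware Regressors on Protein Fitness Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking protein fitness regression the way variant-effect
    practitioners need to: a synthetic epistatic fitness-landscape simulator emulating
    deep mutational scans and iterative engineering campaigns, one-hot and surrogate
    embedding encoders, uncertainty-aware regressors (k-nearest-neighbour, random
    forest with ensemble variance, and exact Gaussian-process regression with linear,
    squared-exponential and Matern-5/2 kernels fitted by MAP with inverse-gamma
    priors), five train/test split protocols (random, positional, mutational,
    fractional and chronological cross-validation), accuracy and calibration metrics
    (adjusted R2, MSE, Spearman rho, reduced chi-squared, calibration curves, expected
    calibration error, sharpness, confidence curves), composition baselines, and an
    expected-improvement Bayesian-optimization assessment loop over labelled candidate
    pools.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
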