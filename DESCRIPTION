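Package: lfpged
Title: Generalized Eigendecomposition Analysis of Multichannel LFP Recordings
Version: 0.1.0
Authors@R:
    person("lfpged", "Maintainers", email = "devnull@example.org",
           role = c("aut", "cre"))
Description: Source separation and inference for multichannel local field
    potential (LFP) recordings from linear electrode arrays. Implements
    generalized eigendecomposition (GED) of stimulus- versus baseline-period
    covariance matrices to extract stimulus-locked mesoscale components,
    trial-label permutation tests for eigenvalue significance, component
    forward-model maps and time series, penalized change-in-mean segmentation
    of component maps with a cut-and-shift permutation test of concordance
    with anatomical contact annotations, Morlet time-frequency decomposition
    with shuffle-based z-scoring and cluster-mass statistics, spectral-profile
    principal component analysis, and a synthetic-session generator with known
    ground-truth subnetworks for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
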