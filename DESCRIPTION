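Package: hfocluster
Title: Unsupervised Detection of High-Frequency Oscillations in Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An unsupervised detector for high-frequency oscillations (HFOs,
    80-500 Hz) in intracranial EEG. Candidate events are screened by
    short-time-energy thresholding, rendered as generalized Morse wavelet
    time-frequency maps whose red channel serves as a 64x64 surrogate image,
    denoised and reconstructed by a convolutional variational auto-encoder,
    and grouped by unsupervised clustering (fuzzy c-means, k-means, Gaussian
    mixtures, mean shift); clusters are assigned to ripple, fast-ripple,
    spike and artifact classes by their mean spectral centroid. Includes a
    synthetic iEEG generator with ground-truth annotations, a minimal EDF
    reader/writer, supervised baselines (k-nearest-neighbour, support vector
    machines), five-fold cross-validation, and an experiment grid for
    representation and hyper-parameter ablations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    mclust,
    class,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
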