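Package: cardiopyramid
Title: Multimodal ECG and PCG Signal Preprocessing and Pyramidal Attention
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for cardiovascular-disease screening from
    paired electrocardiogram (ECG) and phonocardiogram (PCG) recordings.
    Provides signal input/output (WAV, CSV, WFDB, HDF5 segment archives),
    Wiener-filter denoising via the Wiener-Hopf equations, min-max
    normalization, adaptive-threshold false-peak elimination, sliding-window
    segmentation with class-dependent strides, a deterministic synthetic
    ECG/PCG cohort generator, and a 3-D convolutional classifier built from
    pyramidal spectral/spatial/temporal blocks, a tri-pattern attention
    mechanism with weight correction, and a convolutional encoder-decoder
    trained with a joint cross-entropy and reconstruction objective.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils,
    signal,
    rhdf5,
    jsonlite,
    e1071,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
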