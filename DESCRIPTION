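Package: respsound
Title: Adventitious Respiratory Sound Classification from Time-Frequency Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for classifying adventitious respiratory
    sounds (wheezes and crackles) in auscultation recordings. Provides four
    time-frequency front-ends (STFT magnitude spectrogram, Mel-frequency
    cepstral coefficients, constant-Q transform, and a gammatone-filterbank
    cochleogram on the ERB scale), conversion of the resulting matrices to
    viridis-mapped RGB images, an encoder-only Vision Transformer classifier
    implemented in base R with analytic gradients and Adam training, a
    synthetic respiratory-cycle simulator for fully reproducible experiments,
    and an evaluation layer with confusion-matrix metrics, patient-wise
    k-fold cross-validation and non-parametric significance testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    png,
    EBImage,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
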