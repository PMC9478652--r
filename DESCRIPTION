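Package: semgssr
Title: Silent Speech Recognition from Multichannel Surface Electromyography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for sEMG-based silent speech recognition:
    a synthetic multichannel surface-EMG generator emulating a phrase-reading
    acquisition protocol (6 channels, 1 kHz, 2 s epochs, 101 classes, repeated
    sessions, powerline and DC contamination), Butterworth notch and band-pass
    preprocessing, nine sliding-window and spectral feature extractors (MAV,
    VAR, RMS, MWL, TD4, TFD6, STFT, MFCC, MFSC), a Parallel Inception
    Convolutional Neural Network (PICNN) with one inception module per muscle
    channel plus VGG-style and single-trunk inception baselines trained by a
    self-contained batched backpropagation engine, per-class recognition-rate
    evaluation reports, and a subject-based transfer-learning protocol that
    fine-tunes a pretrained network on the leading sessions of a new subject.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
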