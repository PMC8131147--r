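Package: emofuse
Title: Multimodal Emotion Recognition from Facial Expression and EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for arousal-valence emotion recognition from paired
    facial-expression feature sequences and 32-channel EEG. EEG trials are
    wavelet-denoised, segmented, reduced to alpha/beta/theta band powers and
    rendered as scalp topographies; a bilinear convolution network (BCN)
    extracts features from both modalities; a spatial band-attention layer,
    attention-gated LSTMs and a three-layer bidirectional LSTM network fuse
    the two streams; training uses a compound objective built on the
    additive-margin (AM-) softmax loss. Includes a seeded synthetic-data
    generator with the documented arousal-linked band-power structure, so the
    full pipeline is testable without access-restricted affect corpora, plus
    recognition-accuracy, F1 and R-squared evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
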