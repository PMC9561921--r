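Package: stacnn
Title: Two-Stage Audio-Assisted Visual BCI Speller with a
    Spatial-Temporal Attention CNN Decoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for an event-related-potential (ERP) brain-computer
    interface speller that encodes 40 characters with a two-stage,
    space-division multiple access (SDMA) stimulus scheme and decodes
    single-trial responses with a spatial-temporal attention convolutional
    neural network (STA-CNN). Includes the stimulus codebook and trial
    scheduling arithmetic, a synthetic 62-channel EEG session simulator
    with parametric ERP templates and 1/f background noise, the
    preprocessing chain (mastoid re-referencing, 1-30 Hz zero-phase
    band-pass, 200 Hz resampling, baseline-corrected 62 x 100 epochs),
    a from-scratch STA-CNN implementation with temporal and spatial
    attention plus ablation variants, a training/decoding/evaluation
    harness, and a portable binary container for sessions and epochs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
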