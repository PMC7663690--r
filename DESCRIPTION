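Package: spadppg
Title: Remote Photoplethysmography from Single-Photon Camera Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to recover cardiac and respiratory signals from
    low-resolution photon-counting (SPAD) video. Implements facial skin
    segmentation with a small convolutional encoder-decoder trained under an
    asymmetric squared loss, percentile-trimmed masked averaging with offset
    stitching into a one-minute pulse buffer, a fixed two-zero/two-pole
    bandpass over the 0.4-4 Hz heart-rate band, FFT heart-rate estimation,
    beat-peak detection with non-maximal suppression and missing-peak
    recovery, tachogram construction and spline resampling, LF/HF spectral
    balance and respiration-rate estimation, spectral peak-area dependability
    scores for periodic-motion and pulsating-light artifacts, and a
    Pan-Tompkins QRS reference detector with beat-shape and error metrics.
    Includes a physiologically structured simulator of photon-count video
    with ground truth so the whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
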