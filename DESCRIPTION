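Package: semgflex
Title: Surface EMG Gesture Pipeline for Wearable Forearm Band Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An offline processing pipeline for multichannel surface
    electromyography (sEMG) recorded with low-cost four-sensor forearm
    bands: fixed-width datagram framing and 12-bit ADC conversion,
    semicolon-separated session storage, a five-stage movement
    segmentation algorithm driven by extension-burst peaks on the
    reference sensor, two FFT-magnitude feature representations (full
    half-spectrum and 10 Hz band averages), and a two-layer
    sigmoid/softmax feedforward network for six-class hand-gesture
    recognition. Includes a calibrated synthetic cohort generator that
    emulates the acquisition protocol so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
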