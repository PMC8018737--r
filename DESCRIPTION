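Package: v1osc
Title: Analysis of Familiarity-Induced 5-Hz Membrane-Potential Oscillations in V1
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing in-vivo patch-clamp recordings from mouse
    primary visual cortex around stimulus-evoked low-frequency (4-7 Hz)
    membrane-potential oscillations: spike detection and median-filter
    spike removal, FFT power spectra and band magnitudes, complex Morlet
    wavelet time-frequency maps with intertrial phase coherence,
    oscillation-trial detection, split-half resampled orientation and
    direction selectivity indices, Hilbert spike-phase extraction, and
    optogenetic EPSC amplitude/latency extraction with cell-level quality
    filters. Includes a recurrent ring-network firing-rate model with slow
    adaptation that reproduces learning-induced 5-Hz oscillations, reduced
    firing, and enhanced direction selectivity, plus a synthetic-data
    generator producing ground-truth-labelled recordings for testing every
    stage of the pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
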