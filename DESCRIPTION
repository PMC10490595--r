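Package: eegstream
Title: Mobile EEG Telemetry Codec and Resting-State Spectral Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Software model of a 24-channel mobile EEG acquisition chain:
    a seeded synthetic resting-state session generator (occipital alpha,
    frontal delta, blink and saccade artifacts, line noise, 1/f background),
    the firmware-style front end (Butterworth low-pass and band-stop notch
    IIR filters, block-average downsampling from 500 Hz to 250 or 167 Hz,
    first-order high-pass, 24-bit quantization), an adaptive closed-loop
    delta codec with per-channel 4-bit shift selection driven by a floating
    average of difference magnitudes, bit-exact packet framing for the
    telemetry messages (10/14/16-bit channel values, shift updates,
    configuration readback), and an eyes-open versus eyes-closed analysis
    pipeline (1-30 Hz band-pass, 15-s epochs, Hanning-taper power spectral
    density, band powers, cluster-based permutation tests on the channel
    topography).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
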