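Package: semgcodec
Title: Wavelet Sub-Band Compression of Surface Electromyographic Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lossy waveform codec for surface electromyographic (S-EMG)
    recordings. Signals are segmented into fixed-length windows, transformed
    with a periodized orthonormal Daubechies wavelet transform, quantized
    per sub-band with a digital word length drawn from one of four
    decreasing spectral-shape bit-allocation models (linear, square-root,
    exponential, rotated hyperbolic tangent), entropy coded with an adaptive
    arithmetic coder, and packed into a self-describing container. Includes
    compression-factor and percent-residual-difference metrics,
    rate-distortion sweep tooling, a surrogate S-EMG signal generator for
    isometric and dynamic (cycling) protocols, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
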