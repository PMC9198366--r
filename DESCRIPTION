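Package: shiftwave
Title: Translation-Variability Diagnostics for Decimated and Redundant
    Wavelet Transforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decimated (pyramid) and redundant (a trous, undecimated)
    discrete wavelet transforms built from first principles on orthonormal
    Daubechies filter banks with periodic boundary handling, together with a
    diagnostic suite that quantifies the translation variability of multirate
    decompositions: per-subspace full-length reconstructions, FFT
    magnitude-spectrum comparison of shifted inputs, distinct-pattern
    counting, shift-period estimation, linear time-invariance verification,
    and theoretical versus empirical spectral passing bands. Includes
    generators for delta-impulse families and EEG-like surrogate signals so
    every experiment is reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
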