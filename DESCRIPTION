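Package: spadsim
Title: Monte Carlo Simulation and Design of Fluorescence-Lifetime
    Measurements with SPAD Array Detectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulates time-correlated single-photon counting (TCSPC)
    fluorescence-lifetime measurements on single-photon avalanche diode
    (SPAD) array detectors, including excitation-pulse convolution,
    Poisson photon statistics, background events, and the
    one-photon-per-pixel-per-window pile-up mechanism.  Provides
    nonlinear least-squares lifetime fitting with precision and accuracy
    statistics, pile-up scans that locate the maximum tolerable count
    rate per pixel, a time-resolution (rebinning) study, and closed-form
    design calculators for photon budgets (Z'-factor), measurement-window
    duration, total measurement time, and detector data rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
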