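Package: pacbench
Title: Simulation and Surrogate-Based Evaluation of Phase-Amplitude
    Coupling Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates electroencephalography-like signals with controllable
    phase-amplitude cross-frequency coupling implanted into band-limited
    power-law (Brownian) noise, computes four coupling statistics
    (phase-locking value, mean vector length, Kullback-Leibler modulation
    index, and a gamma/log-link spline GLM measure), standardizes them
    against within-trial cut-and-swap surrogate distributions, and runs
    factorial specificity and sensitivity studies over coupling strength,
    modulation width, multimodality, data length, sampling rate, and noise
    level.  Results are returned as tidy tibbles with plotting and
    broom-style tidier methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
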