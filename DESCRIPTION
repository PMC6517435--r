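Package: tvsc
Title: Time-Varying Spatial Coherence for Nonstationary Multivariate Time
    Series
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detection of transient spatial coherence in nonstationary
    multivariate time series. Implements the continuous Morlet wavelet
    transform with signal reconstruction, smoothed pairwise wavelet
    coherence, and a generalized time-varying spatial coherence statistic
    defined as the scaled largest eigenvalue of the matrix of pairwise
    complex coherences at each time-frequency point. Statistical
    significance is assessed by Monte Carlo against nonstationary
    surrogate data obtained by phase randomisation in the wavelet domain
    (preserving both the amplitude distribution and the time-frequency
    modulus of each channel), with a z-test and false discovery rate
    correction restricted to the cone of influence. Includes the
    stationary iAAFT surrogate baseline, simulators for a coupled
    autoregressive benchmark and a network of noisy nonidentical Rossler
    oscillators with a time-varying coupling schedule, and delimited-text
    readers and writers for time-series matrices and time-frequency maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    igraph,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
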