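Package: pupilkinetics
Title: Complexity and Symmetricity Analysis of Pupillary Hippus with a
    Coupled-Lorenz Model of Pupil Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing resting-state pupil-diameter time series
    ('hippus'). Implements epoch-based preprocessing of bilateral 300 Hz
    pupillometry recordings (blink interpolation, quality-control exclusion,
    zero-phase low-pass filtering), sample entropy as a temporal-complexity
    measure, delay-embedded transfer entropy as a left-right symmetricity
    measure, iterative amplitude-adjusted Fourier-transform (IAAFT)
    surrogate testing for nonlinear determinism, and Gaussian-process
    regression with moving-average smoothing to extract the inverted-U
    dependence of both measures on baseline pupil diameter. Also simulates
    a neural controller of pupil diameter in which two coupled Lorenz
    systems drive the locus coeruleus bilaterally, with ipsi- and
    contralateral inhibitory projections to the Edinger-Westphal nuclei,
    and sweeps baseline locus-coeruleus activity to map complexity and
    symmetricity profiles. A synthetic-data generator produces realistic
    bilateral recordings (model-driven or linear autoregressive) so the
    whole pipeline runs without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
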