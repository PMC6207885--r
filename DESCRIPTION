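Package: cmcEEG
Title: Conductance-Based Microcircuit Modelling of EEG Cross-Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Receptor-resolved dynamic causal modelling of resting-state EEG.
    A four-source, four-population conductance-based neural mass network with
    AMPA, GABA-A and NMDA receptor kinetics (including the voltage-dependent
    magnesium-block non-linearity of the NMDA channel) predicts sensor-mode
    cross-spectral densities through linearized transfer functions. Subject
    spectra are fitted by variational Laplace, and group effects on the
    receptor-specific parameters are assessed with canonical variates analysis
    and parametric empirical Bayes with Bayesian model reduction. A synthetic
    cohort generator produces ground-truth recordings and cross-spectra so the
    full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
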