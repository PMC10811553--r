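Package: avnode
Title: Dual-Pathway Atrioventricular Node Model Fitting from RR-Interval Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimation of refractory-period and conduction-delay trends in the
    two pathways of the atrioventricular node during atrial fibrillation, using
    only non-invasive beat series. Provides an event-driven network model of the
    AV node driven by a Poisson atrial impulse train, a Poincare-histogram error
    between observed and simulated RR-interval series, a dynamic genetic
    algorithm for segment-wise parameter fitting, an approximate Bayesian
    computation population Monte Carlo sampler for posterior refinement, a
    simulation-based reduction of model parameters to interpretable
    refractory-period and conduction-delay distributions, and diurnal and
    short-term variability statistics with a drug-outcome feature table. A
    synthetic-data generator emulates 24-hour recordings so the full pipeline is
    testable without patient data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    lhs,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
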