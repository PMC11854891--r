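Package: optews
Title: Ordinal Pattern Transition Entropy as a Local Early-Warning Signal
    for Explosive Synchronization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect impending explosive (first-order-like)
    synchronization transitions in networked dynamical systems from purely
    local measurements. Scalar time series recorded at single nodes are
    symbolized into ordinal patterns (Bandt-Pompe) and characterized by the
    permutation entropy and by the ordinal pattern transition (OPT) entropy,
    the mean entropy of the pattern-to-pattern transition matrix. Measured at
    highly connected "sentinel" nodes, the OPT entropy rises well before the
    phase order parameter shows any sign of the approaching transition.
    The package bundles fixed-step simulators for the three model families
    used to study the effect (Kuramoto phase oscillators, Chialvo neural
    maps, and Roessler chaotic oscillators on star and scale-free graphs
    with degree-correlated heterogeneity), forward/backward adiabatic
    coupling sweeps with hysteresis detection, degree-class entropy
    averages, comparison early-warning statistics (fluctuation standard
    deviation, lag-1 autocorrelation), an alarm rule on the hub-minus-leaf
    entropy difference, and readers for externally recorded (e.g.,
    electronic-circuit) voltage time series.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
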