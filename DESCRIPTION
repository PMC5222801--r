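Package: stdpmod
Title: Neuromodulated Spike-Timing-Dependent Plasticity in Feedforward Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of receptive-field plasticity under
    neuromodulator-gated spike-timing-dependent plasticity (STDP). Provides
    correlated time-varying Poisson input ensembles, a leaky integrate-and-fire
    postsynaptic neuron with a calibrated background noise current, four
    pair-based STDP learning windows (Depression-Potentiation,
    Potentiation-Potentiation, Unchanged-Potentiation, Depression-Unchanged)
    plus a triplet rule, optional weight normalization (multiplicative or
    subtractive), and
    pipeline experiments contrasting the upregulation of learning rate with
    the upregulation of presynaptic activity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
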