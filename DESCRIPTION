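Package: lifmass
Title: Validity Testing of Freeman-Type Neural Mass Models Against Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a noisy conductance-based leaky integrate-and-fire (LIF)
    network on directed Erdos-Renyi graphs, drives two second-order Freeman-type
    neural mass models (a conventional and a modified variant) with the network's
    recorded population spike input, and quantifies the agreement between the
    network's mean membrane potential and each mass model across the connection
    probability / excitatory-fraction parameter plane. Provides spike-contrast
    synchrony, Hamming-windowed averaged power spectra with median frequency and a
    chi-squared comparison statistic, and lag-optimised cross-correlation with
    Fisher-transform significance, plus a sweep pipeline that emits the per-point
    comparison tables.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
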