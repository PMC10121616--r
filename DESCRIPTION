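Package: dendgate
Title: Gated Dendritic Plasticity and Stability in Balanced Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a balanced recurrent network of two-compartment
    (somatic and dendritic) leaky integrate-and-fire pyramidal cells and
    single-compartment inhibitory cells with conductance-based synapses,
    triplet spike-timing-dependent plasticity at perisomatic synapses,
    calcium-spike-dependent plasticity at dendritic synapses driven by
    back-propagating action potentials, and homeostatic modulation of the
    long-term-depression amplitude toward a target firing rate. Provides
    gates on plasticity (learning rate, excitability, spiking threshold,
    inhibition) applicable per compartment and per subpopulation, and a
    stability-analysis layer (explosion factor, critical homeostatic time
    constant, dendritic weight-change accounting, seeded campaign runner)
    for quantifying the plasticity-stability trade-off.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
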