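Package: ffeisim
Title: Spiking Simulations of Paired Feed-Forward Excitation and Delayed Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Leaky integrate-and-fire circuit simulator and spike-train
    spectral analysis for studying how paired feed-forward excitation with
    delayed inhibition (FFEI) transmits high-frequency temporal information,
    compared with feed-forward excitation alone (FFE). Implements
    conductance-based synapses (normalized difference of exponentials),
    two-factor short-term depression, excitation/inhibition balancing,
    inhomogeneous Poisson inputs with rectified sinusoidal rates, circuit
    builders for triad-synapse, multi-level, cortical and XOR architectures,
    and Fourier-coefficient transmission metrics with half-maximum cutoff
    estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
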