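Package: istdpsim
Title: Heterosynaptic Input-Spike-Timing Plasticity and Vestibular Gain Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for anti-Hebbian, heterosynaptic
    input-spike-timing dependent plasticity (iSTDP) at vestibular afferent
    synapses on medial vestibular nucleus neurons. Provides bandpass iSTDP
    kernels (difference-of-Gaussians and difference-of-exponentials) with
    balance and imbalance control, frequency-domain learning-rate functions,
    spike-pair and firing-rate weight-change rules, in-vitro induction
    protocol schedules (input-spike-timing and pause-rebound variants),
    inhomogeneous Poisson spike-train generation, and closed-loop simulations
    of cortex-to-brainstem gain transfer for the vestibulo-ocular reflex,
    including analysis of LTP/LTD imbalance.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
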