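Package: synlut
Title: Look-Up Table Models of Glutamatergic Synapse Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and running look-up-table (LUT) synapse
    models of the glutamatergic receptors AMPAr and NMDAr. Markov kinetic
    state models driven by stereotyped glutamate transients serve as the
    ground-truth generator; their isolated pulse-response amplitudes are
    precomputed over all admissible interpulse-interval patterns into a
    combinadically indexed flat table. At runtime, synaptic responses are
    replayed as amplitude-scaled triple-exponential basis waveforms, with
    receptor current equations including the voltage-dependent magnesium
    block of NMDAr. Includes the full generation tool-chain (memory-window
    calibration, waveform isolation and averaging, FDHM-constrained grid
    search for basis time constants) and a validation harness (Poisson
    inputs, NRMSE accuracy, spike detection, van Rossum spike-train
    distance, point-neuron simulation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
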