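Package: thalacor
Title: State-Dependent Entrainment of Alpha Oscillations in a
    Thalamo-Cortical Network Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a four-population spiking network of the
    thalamo-cortical loop (cortical excitatory and inhibitory cells,
    thalamic relay and reticular populations) with sparse topographic
    Gaussian connectivity, conduction and loop delays, spike-frequency
    adaptation and state-dependent thalamic noise, driven by periodic
    cortical stimulation. Provides spectral, phase-locking and mutual
    information analyses of the simulated EEG and firing rates,
    experiment drivers for thalamic-drive sweeps, stimulation-frequency
    sweeps and Arnold-tongue maps, and an analytically tractable
    delayed-feedback oscillator reduction with Hopf-boundary and
    resonance-curve computations. Results are returned as tibbles with
    broom-style tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
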