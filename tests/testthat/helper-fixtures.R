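# Miniature network (70 neurons) for fast structural/dynamical tests;
# same densities, kernels and dynamics as the full model.
tiny_params <- function(...) {
  tc_params(n_e = 40L, n_i = 10L, n_lgn = 10L, n_rtn = 10L, ...)
}

# EEG spectral peak of a simulation (1 Hz resolution)
sim_peak_hz <- function(sim) eeg_psd(sim)$peak_frequency
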