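#' Mutual information from a cross-spectral correlation
#'
#' Gaussian-channel formula: `SNR = rho / (1 - rho)` and
#' `MI = 1/2 * log2(1 + SNR)` bits. `rho >= 1` (numerical) is clipped
#' just below 1 with a warning; negative `rho` is floored at 0 (MI is
#' then exactly 0).
#'
#' @param rho Cross-spectral correlation in `[-1, 1]`.
#' @return Mutual information in bits (`>= 0`; 0 exactly when
#'   `rho <= 0`).
#' @examples
#' mi_from_rho(0.5) # 0.5 bits
#' mi_from_rho(0.8) # ~1.161 bits
#' @export
mi_from_rho <- function(rho) {
  if (rho >= 1) {
    warn("rho >= 1 clipped below 1")
    rho <- 1 - 1e-12
  }
  if (rho < 0) {
    warn("negative rho floored at 0")
    rho <- 0
  }
  snr <- rho / (1 - rho)
  0.5 * log2(1 + snr)
}

#' Cross-spectral correlation between two traces
#'
#' `rho = Phi_rs(0) / sqrt(Phi_rr(0) * Phi_ss(0))` with the
#' cross-spectral integral evaluated by discrete Fourier transforms of
#' the demeaned traces. With `method = "real"` over the full band this
#' equals the time-domain Pearson correlation (Parseval); with
#' `method = "modulus"` the modulus of the complex cross-spectral sum
#' is taken, so a constant phase lag between the traces does not reduce
#' the correlation. `band` restricts all spectral sums to a frequency
#' band (Hz).
#'
#' @param x,y Equal-length numeric traces (burn-in removed).
#' @param fs Sampling rate in Hz (required if `band` is given).
#' @param band Optional length-2 band in Hz.
#' @param method `"real"` (signed, default) or `"modulus"`.
#' @return Correlation value; in `[-1, 1]` for `"real"`, `[0, 1]` for
#'   `"modulus"`.
#' @export
cross_spectral_rho <- function(x, y, fs = NULL, band = NULL,
                               method = c("real", "modulus")) {
  method <- match.arg(method)
  if (length(x) != length(y)) abort("traces of unequal length")
  n <- length(x)
  xt <- fft(x - mean(x))
  yt <- fft(y - mean(y))
  keep <- rep(TRUE, n)
  if (!is.null(band)) {
    if (is.null(fs)) abort("fs required when band is given")
    freq <- (seq_len(n) - 1) * fs / n
    # one-sided band: keeping the conjugate mirror bins would cancel
    # the imaginary (lag) part of the cross spectrum
    keep <- freq >= band[1] & freq <= band[2] & freq <= fs / 2
    if (!any(keep)) abort("band contains no frequency bins")
  }
  cross <- sum(xt[keep] * Conj(yt[keep]))
  pxx <- sum(Mod(xt[keep])^2)
  pyy <- sum(Mod(yt[keep])^2)
  if (pxx == 0 || pyy == 0) return(0)
  if (method == "real") Re(cross) / sqrt(pxx * pyy)
  else Mod(cross) / sqrt(pxx * pyy)
}

#' Mutual information between stimulation and response traces
#'
#' Computes the cross-spectral correlation [cross_spectral_rho()] and
#' maps it through the Gaussian-channel formula [mi_from_rho()]. The
#' Gaussian assumption (network fluctuations approximately Gaussian at
#' sufficiently high rates) is the model's stated reading of the
#' information carried about the stimulus by the mean firing rate.
#'
#' @inheritParams cross_spectral_rho
#' @param stimulus,response Equal-length traces, burn-in removed.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(stimulus, response, fs = NULL, band = NULL,
                               method = c("real", "modulus")) {
  rho <- cross_spectral_rho(stimulus, response, fs = fs, band = band,
                            method = match.arg(method))
  suppressWarnings(mi_from_rho(rho))
}

#' Stochastic-resonance sweep: mutual information vs noise intensity
#'
#' For each noise intensity `D` (applied to all four populations,
#' including the LGN), runs `trials` independent simulations with the
#' stimulus applied at a random phase, computes per trial the mutual
#' information between the stimulus waveform and the cortical
#' excitatory mean-rate response (band-restricted modulus
#' cross-spectral correlation around the stimulation frequency, so the
#' entrainment phase lag is not penalized), and averages. Stochastic
#' resonance shows as an interior maximum of the curve; dithering would
#' increase monotonically.
#'
#' @param params A `tc_params` object (e.g. [tc_params_small()] for
#'   fast sweeps).
#' @param stim A `tc_stimulus`; the reference weak stimulation is
#'   `S = 0.10` at 11 Hz, and `S = 0` gives the sham control curve.
#' @param D_values Noise intensities to sweep (default 8 log-spaced
#'   values over 1e-4 .. 100, spanning rest-state intensity through
#'   task-state and far enough beyond it to cover both flanks of the
#'   resonance).
#' @param trials Trials per noise level (200 at full scale; use ~20 for
#'   fast runs).
#' @param duration_ms Trial length (analysis window) in ms.
#' @param seed Master seed; spawns per-trial child seeds.
#' @param band_halfwidth_hz Half-width of the spectral band around the
#'   stimulation frequency (default 2 Hz).
#' @param n_boot Bootstrap resamples for the confidence intervals.
#' @return A `tc_micurve` object: tibble `curve` (D, mi, ci_low,
#'   ci_high, n_trials), per-trial values `trial_mi`, the argmax
#'   `D_peak` with bootstrap interval, and the specs used.
#' @export
sr_sweep <- function(params = tc_params_small(),
                     stim = tc_stimulus(0.10, 11),
                     D_values = 10^seq(-4, 2, length.out = 8),
                     trials = 20, duration_ms = 2000, seed = 1L,
                     band_halfwidth_hz = 2, n_boot = 200) {
  stopifnot(inherits(params, "tc_params"), inherits(stim, "tc_stimulus"))
  set.seed(seed)
  nD <- length(D_values)
  child <- matrix(sample.int(2^31 - 2, nD * trials), nD, trials)
  phases <- matrix(runif(nD * trials, 0, 2 * pi), nD, trials)
  band <- c(max(0.5, stim$f_stim - band_halfwidth_hz),
            stim$f_stim + band_halfwidth_hz)
  mi <- matrix(NA_real_, nD, trials)
  for (d in seq_len(nD)) {
    p_d <- params
    p_d$D[] <- D_values[d]
    for (k in seq_len(trials)) {
      st_k <- tc_stimulus(stim$S, stim$f_stim, phases[d, k])
      sim <- tc_simulate(p_d, tc_state("custom", d_lgn = D_values[d]),
                         st_k, duration_ms = duration_ms,
                         seed = child[d, k])
      mi[d, k] <- mutual_information(stim_trace(sim), rate_trace(sim, "e"),
                                     fs = sim$fs, band = band,
                                     method = "modulus")
    }
  }
  boot_means <- array(NA_real_, c(n_boot, nD))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(trials, replace = TRUE)
    boot_means[b, ] <- rowMeans(mi[, idx, drop = FALSE])
  }
  ci <- apply(boot_means, 2, quantile, probs = c(0.025, 0.975))
  curve <- tibble::tibble(
    D = D_values, mi = rowMeans(mi),
    ci_low = ci[1, ], ci_high = ci[2, ], n_trials = trials
  )
  peak_idx <- apply(boot_means, 1, which.max)
  structure(list(
    curve = curve, trial_mi = mi,
    D_peak = D_values[which.max(curve$mi)],
    D_peak_ci = quantile(D_values[peak_idx], probs = c(0.025, 0.975)),
    stim = stim, seed = seed, band = band
  ), class = "tc_micurve")
}

#' @export
print.tc_micurve <- function(x, ...) {
  cat(sprintf("<tc_micurve> S=%g at %g Hz; %d noise levels, %d trials each; MI peak at D = %.3g\n",
              x$stim$S, x$stim$f_stim, nrow(x$curve), x$curve$n_trials[1],
              x$D_peak))
  print(x$curve)
  invisible(x)
}
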