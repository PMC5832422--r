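#' Welch power spectral density of a trace
#'
#' Welch-averaged periodogram: the trace is split into
#' `window_ms`-long segments with fractional overlap `overlap`, each
#' segment is demeaned, tapered (Hann window by default) and
#' transformed with the FFT; the one-sided periodograms are scaled so
#' that the integral of the PSD over frequency equals the time-domain
#' variance (Parseval), then averaged. The spectral peak is the argmax
#' over `peak_band` (DC excluded; the default band covers the
#' physiological EEG range).
#'
#' @param trace Numeric time series (burn-in already removed).
#' @param fs Sampling rate in Hz.
#' @param window_ms Segment length in ms (default 1000, giving 1 Hz
#'   resolution — enough to separate the 8 Hz endogenous rhythm from
#'   11 Hz stimulation).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param window Taper: `"hann"` or `"rectangular"`.
#' @param peak_band Length-2 numeric, frequency band (Hz) searched for
#'   the peak.
#' @param band_powers Named list of bands (Hz) to integrate; default
#'   the 7--9 Hz alpha band around the endogenous frequency.
#' @return A `tc_psd` object: list with `spectrum` (tibble: frequency,
#'   power), `peak_frequency`, `peak_power`, `band_powers`, `total_power`
#'   and method metadata (`window_ms`, `overlap`, `n_segments`,
#'   `resolution_hz`).
#' @examples
#' x <- sin(2 * pi * 8 * seq(0, 2, by = 1e-3))
#' compute_psd(x, fs = 1000)$peak_frequency
#' @export
compute_psd <- function(trace, fs, window_ms = 1000, overlap = 0.5,
                        window = c("hann", "rectangular"),
                        peak_band = c(1, 100),
                        band_powers = list(alpha = c(7, 9))) {
  window <- match.arg(window)
  n <- length(trace)
  nw <- round(window_ms * fs / 1000)
  if (nw > n) abort("trace shorter than one PSD window")
  if (nw < 8) abort("PSD window too short")
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, n - nw + 1L, by = step)
  taper <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))
  } else {
    rep(1, nw)
  }
  u2 <- sum(taper^2)
  acc <- numeric(nw %/% 2 + 1)
  for (s in starts) {
    seg <- trace[s:(s + nw - 1L)]
    seg <- (seg - mean(seg)) * taper
    ft <- fft(seg)[seq_len(nw %/% 2 + 1)]
    # one-sided PSD, power per Hz: integral over f = segment variance
    pg <- (Mod(ft)^2) / (fs * u2)
    pg[-1] <- 2 * pg[-1]
    if (nw %% 2 == 0) pg[length(pg)] <- pg[length(pg)] / 2
    acc <- acc + pg
  }
  psd <- acc / length(starts)
  freq <- (seq_along(psd) - 1) * fs / nw
  df <- fs / nw
  sel <- freq >= peak_band[1] & freq <= peak_band[2] & freq > 0
  if (!any(sel)) abort("peak_band contains no frequency bins")
  pk <- which(sel)[which.max(psd[sel])]
  bp <- vapply(band_powers, function(b) {
    sum(psd[freq >= b[1] & freq <= b[2]]) * df
  }, numeric(1))
  structure(list(
    spectrum = tibble::tibble(frequency = freq, power = psd),
    peak_frequency = freq[pk], peak_power = psd[pk],
    band_powers = as.list(bp), total_power = sum(psd) * df,
    window_ms = window_ms, overlap = overlap, window = window,
    n_segments = length(starts), resolution_hz = df, fs = fs
  ), class = "tc_psd")
}

#' @export
print.tc_psd <- function(x, ...) {
  cat(sprintf("<tc_psd> peak %.2f Hz (power %.3g); %d x %g ms windows, %g Hz resolution\n",
              x$peak_frequency, x$peak_power, x$n_segments, x$window_ms,
              x$resolution_hz))
  invisible(x)
}

#' PSD value at (the bin nearest) a frequency
#'
#' Used to track power at the endogenous alpha frequency and at the
#' stimulation frequency across sweeps. DC is excluded.
#'
#' @param summary A `tc_psd` object.
#' @param f Frequency in Hz, `> 0` and within the spectral range.
#' @return Power density at the nearest frequency bin.
#' @export
power_at <- function(summary, f) {
  stopifnot(inherits(summary, "tc_psd"))
  freq <- summary$spectrum$frequency
  if (f <= 0) abort("f must be > 0 (DC excluded)")
  if (f > max(freq)) abort("f outside spectral range")
  summary$spectrum$power[which.min(abs(freq - f))]
}

#' Detect a spectral peak above background
#'
#' Locates the PSD maximum within `band` and classifies it as
#' detectable when it exceeds `prominence` times the median PSD over
#' `reference_band` (a flat, suppressed spectrum — e.g. the
#' task-engaged state — has no detectable alpha peak).
#'
#' @param psd A `tc_psd` object.
#' @param band Search band (Hz) for the peak.
#' @param reference_band Band (Hz) whose median power defines the
#'   background.
#' @param prominence Detection threshold (peak / background ratio).
#' @return List with `frequency`, `power`, `background`, `detected`.
#' @export
detect_spectral_peak <- function(psd, band = c(4, 15),
                                 reference_band = c(1, 30),
                                 prominence = 3) {
  stopifnot(inherits(psd, "tc_psd"))
  freq <- psd$spectrum$frequency
  pw <- psd$spectrum$power
  sel <- freq >= band[1] & freq <= band[2]
  ref <- freq >= reference_band[1] & freq <= reference_band[2]
  i <- which(sel)[which.max(pw[sel])]
  bg <- median(pw[ref])
  list(frequency = freq[i], power = pw[i], background = bg,
       detected = pw[i] >= prominence * bg)
}

#' EEG spectral summary of a simulation
#'
#' Convenience wrapper: [compute_psd()] on the post-burn-in EEG trace.
#'
#' @param sim A `tc_sim` object.
#' @param ... Passed to [compute_psd()].
#' @return A `tc_psd` object.
#' @export
eeg_psd <- function(sim, ...) {
  compute_psd(eeg_trace(sim), fs = sim$fs, ...)
}

# Exponentially smoothed per-neuron rate traces (1 ms bins) from the
# spike raster, reusing the model's synaptic kernel tau_m.
.neuron_rate_traces <- function(sim, population = "e", n_neurons = 50,
                                tau_ms = sim$params$tau_m) {
  sizes <- sim$network$sizes
  offset <- c(e = 0L, i = sizes[["e"]],
              lgn = sizes[["e"]] + sizes[["i"]],
              rtn = sizes[["e"]] + sizes[["i"]] + sizes[["lgn"]])
  ids <- offset[[population]] + seq_len(min(n_neurons, sizes[[population]]))
  rast <- sim$raster[sim$raster$neuron %in% ids &
                       sim$raster$time > sim$burn_in_ms, ]
  n_bins <- floor(sim$duration_ms)
  bins <- pmin(n_bins, pmax(1L, ceiling(rast$time - sim$burn_in_ms)))
  counts <- matrix(0, n_bins, length(ids))
  idx <- match(rast$neuron, ids)
  for (k in seq_along(bins)) counts[bins[k], idx[k]] <- counts[bins[k], idx[k]] + 1
  # exponential smoothing (discrete-time filter, 1 ms steps)
  decay <- exp(-1 / tau_ms)
  apply(counts, 2, function(x) as.numeric(stats::filter(x, decay,
                                                        method = "recursive")))
}

#' Mean pairwise firing-rate correlation of cortical excitatory cells
#'
#' Single-neuron spike trains are convolved with the model's
#' exponential synaptic kernel (`tau_m`), binned at 1 ms, and all
#' unordered pairs of neurons are correlated (Pearson); the mean over
#' pairs is returned. Zero-variance traces are excluded with a warning.
#'
#' @param sim A `tc_sim` object, or a numeric matrix of rate traces
#'   (columns = neurons).
#' @param population Population to use when `sim` is a simulation.
#' @param n_neurons Number of neurons to include (subsampled for speed).
#' @param smooth_ms Smoothing kernel time constant (ms); recorded in
#'   the attribute `smooth_ms`.
#' @return Mean pairwise correlation (scalar, in `[-1, 1]`).
#' @export
rate_correlations <- function(sim, population = "e", n_neurons = 50,
                              smooth_ms = NULL) {
  if (inherits(sim, "tc_sim")) {
    if (is.null(smooth_ms)) smooth_ms <- sim$params$tau_m
    m <- .neuron_rate_traces(sim, population, n_neurons, tau_ms = smooth_ms)
  } else {
    m <- as.matrix(sim)
    if (is.null(smooth_ms)) smooth_ms <- NA_real_
  }
  if (ncol(m) < 2) abort("need at least 2 neurons for pairwise correlations")
  v <- apply(m, 2, stats::var)
  if (any(v == 0)) {
    warn(sprintf("%d zero-variance trace(s) excluded from correlation",
                 sum(v == 0)))
    m <- m[, v > 0, drop = FALSE]
    if (ncol(m) < 2) abort("fewer than 2 non-degenerate traces")
  }
  cm <- cor(m)
  out <- mean(cm[upper.tri(cm)])
  attr(out, "smooth_ms") <- smooth_ms
  out
}
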