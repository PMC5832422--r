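#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation into long population-rate format
#'
#' @param x A `tc_sim` object.
#' @param ... Unused.
#' @return Tibble: `time_ms`, `population`, `rate`, `eeg` (EEG
#'   repeated per population row is avoided: population `"eeg"` holds
#'   the EEG trace in the `rate` column scale-free).
#' @exportS3Method
tidy.tc_sim <- function(x, ...) {
  keep <- x$time > x$burn_in_ms
  rates <- tibble::as_tibble(x$rates[keep, , drop = FALSE])
  dplyr::bind_rows(
    tidyr::pivot_longer(
      dplyr::mutate(rates, time_ms = x$time[keep]),
      cols = -"time_ms", names_to = "population", values_to = "value"
    ) |> dplyr::mutate(signal = "rate"),
    tibble::tibble(time_ms = x$time[keep], population = "eeg",
                   value = x$eeg[keep], signal = "eeg")
  )
}

#' @exportS3Method
glance.tc_sim <- function(x, ...) {
  keep <- x$time > x$burn_in_ms
  tibble::tibble(
    state = x$state$label, d_lgn = x$state$d_lgn, S = x$stim$S,
    f_stim = x$stim$f_stim, duration_ms = x$duration_ms,
    seed = x$seed, n_neurons = sum(x$network$sizes),
    n_spikes = nrow(x$raster),
    rate_e = mean(x$rates[keep, "e"]), rate_i = mean(x$rates[keep, "i"]),
    rate_lgn = mean(x$rates[keep, "lgn"]),
    rate_rtn = mean(x$rates[keep, "rtn"])
  )
}

#' @exportS3Method
tidy.tc_psd <- function(x, ...) x$spectrum

#' @exportS3Method
glance.tc_psd <- function(x, ...) {
  tibble::tibble(
    peak_frequency = x$peak_frequency, peak_power = x$peak_power,
    total_power = x$total_power,
    !!!setNames(as.numeric(x$band_powers),
                paste0("power_", names(x$band_powers))),
    window_ms = x$window_ms, n_segments = x$n_segments,
    resolution_hz = x$resolution_hz
  )
}

#' @exportS3Method
tidy.tc_phase <- function(x, ...) x$phases

#' @exportS3Method
glance.tc_phase <- function(x, ...) {
  tibble::tibble(
    n_trials = x$n_trials, f = x$f, f_used = x$f_used,
    circular_variance = x$circular_variance,
    preferred_phase = x$preferred_phase, p_value = x$p_value
  )
}

#' @exportS3Method
tidy.tc_micurve <- function(x, ...) x$curve

#' @exportS3Method
glance.tc_micurve <- function(x, ...) {
  tibble::tibble(
    S = x$stim$S, f_stim = x$stim$f_stim,
    D_peak = x$D_peak, D_peak_low = x$D_peak_ci[[1]],
    D_peak_high = x$D_peak_ci[[2]],
    mi_max = max(x$curve$mi), mi_min = min(x$curve$mi)
  )
}

#' @exportS3Method
tidy.tc_tongue <- function(x, ...) x$map

#' @exportS3Method
glance.tc_tongue <- function(x, ...) {
  tibble::tibble(
    state = x$state, entrained_fraction = x$entrained_fraction,
    n_cells = nrow(x$map), tol_hz = x$tol_hz, endog_hz = x$endog_hz
  )
}

#' Tidy a network graph into its edge list
#'
#' @param x A `tc_network` object.
#' @param ... Unused.
#' @return The edge tibble.
#' @exportS3Method
tidy.tc_network <- function(x, ...) x$edges

#' @exportS3Method
glance.tc_network <- function(x, ...) {
  tibble::tibble(
    n_neurons = sum(x$sizes), n_edges = nrow(x$edges),
    max_delay_ms = max(x$edges$delay_ms), seed = x$seed
  )
}
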