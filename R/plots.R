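#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_ribbon
#'   geom_tile geom_histogram geom_vline labs scale_x_log10
#'   scale_fill_viridis_c facet_wrap theme_minimal
NULL

#' Plot a simulation: EEG and population mean rates
#'
#' @param object A `tc_sim` object.
#' @param ... Unused.
#' @return A ggplot object (facets: EEG trace and population rates).
#' @exportS3Method
autoplot.tc_sim <- function(object, ...) {
  df <- tidy.tc_sim(object)
  ggplot(df, aes(x = .data$time_ms, y = .data$value,
                 colour = .data$population)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~signal, ncol = 1, scales = "free_y") +
    labs(x = "time (ms)", y = NULL,
         title = sprintf("%s state, S = %g, f = %g Hz",
                         object$state$label, object$stim$S,
                         object$stim$f_stim)) +
    theme_minimal()
}

#' Plot a power spectral density with its peak
#'
#' @param object A `tc_psd` object.
#' @param fmax Upper frequency limit of the plot (Hz).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.tc_psd <- function(object, fmax = 50, ...) {
  df <- dplyr::filter(object$spectrum, .data$frequency <= fmax)
  ggplot(df, aes(x = .data$frequency, y = .data$power)) +
    geom_line() +
    geom_vline(xintercept = object$peak_frequency, linetype = 2,
               colour = "red") +
    labs(x = "frequency (Hz)", y = "power spectral density",
         subtitle = sprintf("peak %.1f Hz", object$peak_frequency)) +
    theme_minimal()
}

#' Plot a phase-difference distribution
#'
#' @param object A `tc_phase` object.
#' @param bins Histogram bins over `(-pi, pi]`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.tc_phase <- function(object, bins = 24, ...) {
  ggplot(object$phases, aes(x = .data$dphi)) +
    geom_histogram(bins = bins, boundary = -pi, fill = "grey40") +
    geom_vline(xintercept = object$preferred_phase, colour = "red",
               linetype = 2) +
    labs(x = expression(Delta * phi ~ "(rad)"), y = "trials",
         subtitle = sprintf("circular variance %.2f%s",
                            object$circular_variance,
                            if (!is.na(object$p_value))
                              sprintf(", shuffle p = %.3g", object$p_value)
                            else "")) +
    theme_minimal()
}

#' Plot a mutual-information (stochastic resonance) curve
#'
#' @param object A `tc_micurve` object.
#' @param ... Unused.
#' @return A ggplot object (MI vs noise intensity, log x, bootstrap
#'   ribbon).
#' @exportS3Method
autoplot.tc_micurve <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$D, y = .data$mi)) +
    geom_ribbon(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                alpha = 0.25) +
    geom_line() + geom_point() +
    scale_x_log10() +
    labs(x = "noise intensity D", y = "mutual information (bits)",
         subtitle = sprintf("S = %g at %g Hz; MI peak at D = %.3g",
                            object$stim$S, object$stim$f_stim,
                            object$D_peak)) +
    theme_minimal()
}

#' Plot an Arnold-tongue map
#'
#' @param object A `tc_tongue` object.
#' @param fill `"peak_frequency"`, `"peak_power"` or `"entrained"`.
#' @param ... Unused.
#' @return A ggplot object (tile map over stimulation frequency and
#'   amplitude).
#' @exportS3Method
autoplot.tc_tongue <- function(object, fill = "peak_frequency", ...) {
  ggplot(object$map, aes(x = .data$f_stim, y = .data$S,
                         fill = .data[[fill]])) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = "stimulation frequency (Hz)", y = "stimulation amplitude S",
         fill = fill,
         title = sprintf("%s state (%.0f%% entrained)", object$state,
                         100 * object$entrained_fraction)) +
    theme_minimal()
}

#' Plot rest vs task resonance curves of the reduced oscillator
#'
#' @param curves Output of [rest_vs_task_curves()].
#' @return A ggplot object.
#' @export
plot_resonance_curves <- function(curves) {
  ggplot(curves, aes(x = .data$f_hz, y = .data$amplitude,
                     colour = .data$regime)) +
    geom_line() +
    labs(x = "forcing frequency (Hz)", y = "entrained amplitude |U|") +
    theme_minimal()
}
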