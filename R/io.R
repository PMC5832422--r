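.write_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Persist a simulation result as CSV + sidecar metadata
#'
#' Writes `eeg.csv` (time_ms, eeg), `rates.csv` (time_ms and one
#' column per population), `raster.csv` (time_ms, population, neuron),
#' `params.yaml` and `meta.json` (state, stimulus, seed, burn-in) into
#' `dir`.
#'
#' @param sim A `tc_sim` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "tc_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_csv(tibble::tibble(time_ms = sim$time, eeg = sim$eeg),
             file.path(dir, "eeg.csv"))
  .write_csv(tibble::tibble(time_ms = sim$time,
                            tibble::as_tibble(sim$rates)),
             file.path(dir, "rates.csv"))
  .write_csv(sim$raster, file.path(dir, "raster.csv"))
  write_params(sim$params, file.path(dir, "params.yaml"))
  jsonlite::write_json(
    list(state = unclass(sim$state), stim = unclass(sim$stim),
         seed = sim$seed, burn_in_ms = sim$burn_in_ms,
         duration_ms = sim$duration_ms, fs = sim$fs),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Persist a spectral summary as CSV + JSON sidecar
#'
#' @param psd A `tc_psd` object.
#' @param stem Output path stem; writes `<stem>.csv` (frequency,
#'   power) and `<stem>.json` (peak, band powers, method metadata).
#' @return `stem`, invisibly.
#' @export
write_psd <- function(psd, stem) {
  stopifnot(inherits(psd, "tc_psd"))
  .write_csv(psd$spectrum, paste0(stem, ".csv"))
  meta <- psd[c("peak_frequency", "peak_power", "band_powers",
                "total_power", "window_ms", "overlap", "n_segments",
                "resolution_hz", "fs")]
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' Persist a phase distribution as CSV + JSON sidecar
#'
#' @param ph A `tc_phase` object.
#' @param stem Output path stem; writes `<stem>.csv` (per-trial
#'   phases) and `<stem>.json` (circular variance, preferred phase,
#'   p-value, analysis settings).
#' @return `stem`, invisibly.
#' @export
write_phase <- function(ph, stem) {
  stopifnot(inherits(ph, "tc_phase"))
  .write_csv(ph$phases, paste0(stem, ".csv"))
  meta <- ph[c("circular_variance", "preferred_phase", "f", "f_used",
               "window_ms", "n_trials", "p_value")]
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}
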