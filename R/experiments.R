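# deterministic child seeds from a master seed
.spawn_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2^31 - 2, n)
}

#' Thalamic-drive sweep
#'
#' Simulates the network across a range of LGN noise intensities
#' (sham or stimulated), and summarizes each run: alpha-band EEG
#' power, power at the endogenous frequency and (if stimulated) at the
#' stimulation frequency, EEG peak frequency/power, mean cortical and
#' sub-cortical firing rates, and the mean pairwise excitatory rate
#' correlation. With increasing drive the endogenous alpha power
#' falls, firing rates rise, and (under stimulation) spectral power
#' migrates to the stimulation frequency.
#'
#' @param params A `tc_params` object.
#' @param d_lgn_values LGN noise intensities (default 5 log-spaced
#'   values over 1e-4 .. 1).
#' @param seeds Integer seeds; each (intensity, seed) pair is one run.
#' @param stim A `tc_stimulus` (default sham).
#' @param duration_ms Analysis duration per run.
#' @param alpha_band Band (Hz) integrated as "alpha power".
#' @param endog_hz Endogenous peak frequency tracked via [power_at()].
#' @param corr_neurons Excitatory neurons used for the pairwise
#'   correlation (0 to skip).
#' @return A `tc_sweep` tibble: one row per run with columns `d_lgn`,
#'   `seed`, `alpha_power`, `power_endog`, `power_stim`,
#'   `peak_frequency`, `peak_power`, `rate_e`, `rate_i`, `rate_lgn`,
#'   `rate_rtn`, `rate_corr`, `failed`.
#' @export
drive_sweep <- function(params = tc_params(),
                        d_lgn_values = 10^seq(-4, 0, length.out = 5),
                        seeds = 1:3, stim = tc_stimulus(),
                        duration_ms = 2000, alpha_band = c(7, 9),
                        endog_hz = 8, corr_neurons = 40) {
  grid <- tidyr::expand_grid(d_lgn = d_lgn_values, seed = seeds)
  rows <- purrr::pmap(grid, function(d_lgn, seed) {
    tryCatch({
      sim <- tc_simulate(params, tc_state("custom", d_lgn = d_lgn), stim,
                         duration_ms = duration_ms, seed = seed)
      psd <- eeg_psd(sim, band_powers = list(alpha = alpha_band))
      rc <- if (corr_neurons >= 2)
        suppressWarnings(as.numeric(rate_correlations(sim, "e", corr_neurons)))
      else NA_real_
      tibble::tibble(
        d_lgn = d_lgn, seed = seed,
        alpha_power = psd$band_powers$alpha,
        power_endog = power_at(psd, endog_hz),
        power_stim = if (stim$S > 0) power_at(psd, stim$f_stim) else NA_real_,
        peak_frequency = psd$peak_frequency, peak_power = psd$peak_power,
        rate_e = mean(rate_trace(sim, "e")),
        rate_i = mean(rate_trace(sim, "i")),
        rate_lgn = mean(rate_trace(sim, "lgn")),
        rate_rtn = mean(rate_trace(sim, "rtn")),
        rate_corr = rc, failed = FALSE
      )
    }, error = function(e) {
      warn(paste0("sweep point failed (d_lgn=", d_lgn, ", seed=", seed,
                  "): ", conditionMessage(e)))
      tibble::tibble(d_lgn = d_lgn, seed = seed, alpha_power = NA_real_,
                     power_endog = NA_real_, power_stim = NA_real_,
                     peak_frequency = NA_real_, peak_power = NA_real_,
                     rate_e = NA_real_, rate_i = NA_real_,
                     rate_lgn = NA_real_, rate_rtn = NA_real_,
                     rate_corr = NA_real_, failed = TRUE)
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tc_sweep", class(out))
  attr(out, "stim") <- stim
  out
}

#' Stimulation-frequency sweep
#'
#' Fixed amplitude, frequency varied: per frequency the full EEG PSD
#' is retained together with the power at the stimulation frequency
#' and at the endogenous frequency. In the rest state power stays
#' concentrated at the endogenous rhythm unless the stimulation is
#' close to it; in the task state power follows the stimulation
#' frequency.
#'
#' @inheritParams drive_sweep
#' @param state A `tc_state`.
#' @param S Stimulation amplitude.
#' @param f_values Stimulation frequencies (Hz); empty gives an empty
#'   result without simulating.
#' @param seeds Seeds (one run per frequency x seed).
#' @return A `tc_sweep` tibble with columns `f_stim`, `seed`,
#'   `power_stim`, `power_endog`, `peak_frequency`, `peak_power`,
#'   `psd` (list column of `tc_psd`), `failed`.
#' @export
frequency_sweep <- function(params = tc_params(), state = tc_state("rest"),
                            S = 0.15, f_values = seq(0, 50, by = 5),
                            seeds = 1L, duration_ms = 2000, endog_hz = 8) {
  if (length(f_values) == 0) {
    out <- tibble::tibble(f_stim = numeric(0), seed = integer(0),
                          power_stim = numeric(0), power_endog = numeric(0),
                          peak_frequency = numeric(0), peak_power = numeric(0),
                          psd = list(), failed = logical(0))
    class(out) <- c("tc_sweep", class(out))
    return(out)
  }
  grid <- tidyr::expand_grid(f_stim = f_values, seed = seeds)
  rows <- purrr::pmap(grid, function(f_stim, seed) {
    tryCatch({
      sim <- tc_simulate(params, state, tc_stimulus(S, f_stim),
                         duration_ms = duration_ms, seed = seed)
      psd <- eeg_psd(sim)
      tibble::tibble(
        f_stim = f_stim, seed = seed,
        power_stim = if (f_stim > 0) power_at(psd, f_stim) else NA_real_,
        power_endog = power_at(psd, endog_hz),
        peak_frequency = psd$peak_frequency, peak_power = psd$peak_power,
        psd = list(psd), failed = FALSE
      )
    }, error = function(e) {
      warn(paste0("frequency point failed (f=", f_stim, "): ",
                  conditionMessage(e)))
      tibble::tibble(f_stim = f_stim, seed = seed, power_stim = NA_real_,
                     power_endog = NA_real_, peak_frequency = NA_real_,
                     peak_power = NA_real_, psd = list(NULL), failed = TRUE)
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tc_sweep", class(out))
  out
}

#' Arnold-tongue map over stimulation amplitude and frequency
#'
#' For every cell of the (S, f_stim) grid the network is simulated and
#' the EEG PSD peak located. A cell is classified as entrained when
#' the peak frequency lies within `tol_hz` (default one PSD bin) of
#' the stimulation frequency and the stimulation frequency itself is
#' more than `tol_hz` away from the endogenous rhythm (where
#' entrainment and resonance are indistinguishable). The map is
#' written incrementally to `checkpoint` (CSV) if given, and a rerun
#' resumes from the completed cells.
#'
#' @inheritParams frequency_sweep
#' @param S_grid,f_grid Grid values within `[0, 0.5]` and `[0, 50]` Hz.
#' @param seed Master seed; each cell gets a deterministic child seed,
#'   matched across states for equal grids and master seed.
#' @param tol_hz Entrainment tolerance (default: one PSD bin of the
#'   1 s Welch window, 1 Hz).
#' @param checkpoint Optional CSV path for incremental/resumable maps.
#' @return A `tc_tongue` object: tibble `map` (S, f_stim, seed,
#'   peak_frequency, peak_power, entrained, failed) plus grid metadata
#'   and the entrained fraction.
#' @export
arnold_tongue <- function(params = tc_params(), state = tc_state("rest"),
                          S_grid = seq(0, 0.5, length.out = 10),
                          f_grid = seq(0, 50, length.out = 10),
                          seed = 1L, duration_ms = 2000, endog_hz = 8,
                          tol_hz = 1, checkpoint = NULL) {
  grid <- tidyr::expand_grid(S = S_grid, f_stim = f_grid)
  grid$cell_seed <- .spawn_seeds(seed, nrow(grid))
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- tibble::as_tibble(utils::read.csv(checkpoint))
  }
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    S <- grid$S[i]; f_stim <- grid$f_stim[i]; cs <- grid$cell_seed[i]
    if (!is.null(done)) {
      hit <- done[abs(done$S - S) < 1e-12 &
                    abs(done$f_stim - f_stim) < 1e-12 & !done$failed, ]
      if (nrow(hit) >= 1) {
        rows[[i]] <- tibble::as_tibble(hit[1, ])
        next
      }
    }
    row <- tryCatch({
      sim <- tc_simulate(params, state, tc_stimulus(S, f_stim),
                         duration_ms = duration_ms, seed = cs)
      psd <- eeg_psd(sim)
      tibble::tibble(
        S = S, f_stim = f_stim, seed = cs,
        peak_frequency = psd$peak_frequency, peak_power = psd$peak_power,
        entrained = S > 0 & f_stim > 0 &
          abs(psd$peak_frequency - f_stim) <= tol_hz &
          abs(f_stim - endog_hz) > tol_hz,
        failed = FALSE
      )
    }, error = function(e) {
      warn(paste0("tongue cell failed (S=", S, ", f=", f_stim, "): ",
                  conditionMessage(e)))
      tibble::tibble(S = S, f_stim = f_stim, seed = cs,
                     peak_frequency = NA_real_, peak_power = NA_real_,
                     entrained = NA, failed = TRUE)
    })
    rows[[i]] <- row
    if (!is.null(checkpoint)) {
      has_file <- file.exists(checkpoint)
      utils::write.table(row, checkpoint, sep = ",", row.names = FALSE,
                         col.names = !has_file, append = has_file)
    }
  }
  map <- dplyr::bind_rows(rows)
  structure(list(
    map = map, state = state$label, S_grid = S_grid, f_grid = f_grid,
    seed = seed, tol_hz = tol_hz, endog_hz = endog_hz,
    entrained_fraction = mean(map$entrained, na.rm = TRUE)
  ), class = "tc_tongue")
}

#' @export
print.tc_tongue <- function(x, ...) {
  cat(sprintf("<tc_tongue> %s state, %dx%d grid: %.1f%% of cells entrained\n",
              x$state, length(x$S_grid), length(x$f_grid),
              100 * x$entrained_fraction))
  invisible(x)
}

#' Phase-locking experiment across independent trials
#'
#' Runs `n_trials` independent seeded simulations with the stimulus
#' applied at a random phase per trial, and feeds the cortical
#' excitatory mean-rate responses and stimulus waveforms to
#' [phase_locking()] followed by [shuffle_significance()]. In the
#' task state the phase-difference distribution clusters sharply; in
#' the rest state it is near-uniform.
#'
#' @inheritParams frequency_sweep
#' @param S,f_stim Stimulation amplitude and frequency.
#' @param n_trials Number of independent trials (200 at full scale).
#' @param seed Master seed.
#' @param window_ms Analysis window for the windowed DFT.
#' @param n_shuffles Shuffles for the significance test.
#' @return A `tc_phase` object (with `p_value` filled).
#' @export
phase_experiment <- function(params = tc_params(), state = tc_state("task"),
                             S = 0.1, f_stim = 11, n_trials = 200,
                             seed = 1L, duration_ms = 2000,
                             window_ms = 500, n_shuffles = 500) {
  set.seed(seed)
  child <- sample.int(2^31 - 2, n_trials)
  phases0 <- runif(n_trials, 0, 2 * pi)
  fs <- NULL
  trials <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    sim <- tc_simulate(params, state, tc_stimulus(S, f_stim, phases0[k]),
                       duration_ms = duration_ms, seed = child[k])
    fs <- sim$fs
    trials[[k]] <- list(response = rate_trace(sim, "e"),
                        stimulus = stim_trace(sim))
  }
  set.seed(seed + 1L)  # window placement + shuffles
  dist <- phase_locking(trials, f = f_stim, window_ms = window_ms, fs = fs)
  shuffle_significance(dist, n_shuffles = n_shuffles)
}

#' Run the full experiment battery
#'
#' Executes the standard set of in-silico experiments (rest/task
#' baseline spectra, sham and stimulated thalamic-drive sweeps,
#' stimulation-frequency sweeps, Arnold-tongue maps for both states,
#' phase-locking experiments, and the stochastic-resonance noise
#' sweep) at a scaled-down (`"smoke"`) or full-scale (`"full"`)
#' preset, writing CSV outputs and a JSON manifest (config, seeds,
#' per-experiment status, file inventory) to `output_dir`.
#'
#' @param output_dir Writable output directory (created if absent).
#' @param preset `"smoke"` (quarter-size network, few points/trials;
#'   minutes on one CPU) or `"full"` (full-size network and trial counts).
#' @param seed Master seed.
#' @param params Optional `tc_params` overriding the preset network.
#' @return The manifest (list), invisibly. Each experiment's `status`
#'   is `"ok"` or the error message; any failure is reflected in the
#'   manifest `ok` flag.
#' @export
run_all <- function(output_dir, preset = c("smoke", "full"), seed = 1L,
                    params = NULL) {
  preset <- match.arg(preset)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(params))
    params <- if (preset == "smoke") tc_params_small() else tc_params()
  cfg <- list(preset = preset, seed = seed, params = unclass(params))
  n_trials <- if (preset == "smoke") 20 else 200
  grid_n <- if (preset == "smoke") 6 else 10
  sweep_seeds <- if (preset == "smoke") 1:2 else 1:3
  sr_trials <- if (preset == "smoke") 10 else 20

  steps <- list(
    rest_psd = function() {
      sim <- tc_simulate(params, tc_state("rest"), seed = seed)
      write_psd(eeg_psd(sim), file.path(output_dir, "rest_psd"))
    },
    task_stim_psd = function() {
      sim <- tc_simulate(params, tc_state("task"), tc_stimulus(0.15, 11),
                         seed = seed)
      write_psd(eeg_psd(sim), file.path(output_dir, "task_stim_psd"))
    },
    drive_sham = function() {
      sw <- drive_sweep(params, seeds = sweep_seeds)
      .write_csv(sw, file.path(output_dir, "drive_sweep_sham.csv"))
    },
    drive_stim = function() {
      sw <- drive_sweep(params, seeds = sweep_seeds,
                        stim = tc_stimulus(0.15, 11))
      .write_csv(sw, file.path(output_dir, "drive_sweep_stim.csv"))
    },
    freq_sweep = function() {
      for (st in c("rest", "task")) {
        sw <- frequency_sweep(params, tc_state(st),
                              f_values = seq(0, 50, length.out = grid_n))
        .write_csv(dplyr::select(sw, -"psd"),
                   file.path(output_dir, paste0("freq_sweep_", st, ".csv")))
      }
    },
    tongue = function() {
      for (st in c("rest", "task")) {
        tg <- arnold_tongue(params, tc_state(st),
                            S_grid = seq(0, 0.5, length.out = grid_n),
                            f_grid = seq(0, 50, length.out = grid_n),
                            seed = seed)
        .write_csv(tg$map, file.path(output_dir, paste0("tongue_", st, ".csv")))
      }
    },
    phase = function() {
      for (st in c("rest", "task")) {
        ph <- phase_experiment(params, tc_state(st), n_trials = n_trials,
                               seed = seed)
        write_phase(ph, file.path(output_dir, paste0("phase_", st)))
      }
    },
    sr = function() {
      mc <- sr_sweep(params, trials = sr_trials, seed = seed)
      .write_csv(mc$curve, file.path(output_dir, "mi_curve_stim.csv"))
      mc0 <- sr_sweep(params, stim = tc_stimulus(0, 11), trials = sr_trials,
                      seed = seed)
      .write_csv(mc0$curve, file.path(output_dir, "mi_curve_sham.csv"))
    }
  )

  status <- list()
  for (nm in names(steps)) {
    message(format(Sys.time(), "%H:%M:%S"), " running ", nm, " ...")
    status[[nm]] <- tryCatch({
      steps[[nm]]()
      "ok"
    }, error = function(e) conditionMessage(e))
  }
  cfg_path <- file.path(output_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = seed, preset = preset, status = status,
    ok = all(unlist(status) == "ok"),
    files = list.files(output_dir),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
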