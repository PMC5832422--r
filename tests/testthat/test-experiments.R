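test_that("a single-point sweep equals a direct simulate-and-analyze call", {
  p <- tc_params_small()
  sw <- drive_sweep(p, d_lgn_values = 1e-4, seeds = 7L, duration_ms = 1000,
                    corr_neurons = 0)
  sim <- tc_simulate(p, tc_state("custom", d_lgn = 1e-4), tc_stimulus(),
                     duration_ms = 1000, seed = 7L)
  psd <- eeg_psd(sim, band_powers = list(alpha = c(7, 9)))
  expect_equal(sw$alpha_power, psd$band_powers$alpha)
  expect_equal(sw$peak_frequency, psd$peak_frequency)
  expect_equal(sw$rate_e, mean(rate_trace(sim, "e")))
  expect_false(sw$failed)
})

test_that("an empty frequency sweep runs no simulations", {
  out <- frequency_sweep(tc_params_small(), f_values = numeric(0))
  expect_equal(nrow(out), 0)
  expect_true(all(c("f_stim", "power_stim", "failed") %in% names(out)))
})

test_that("sham cells are never classified as entrained", {
  p <- tiny_params()
  tg <- arnold_tongue(p, tc_state("rest"), S_grid = c(0, 0.3),
                      f_grid = c(0, 20), duration_ms = 1000, seed = 2)
  sham_rows <- tg$map[tg$map$S == 0 | tg$map$f_stim == 0, ]
  expect_true(all(!sham_rows$entrained))
  expect_equal(nrow(tg$map), 4)
})

test_that("a resumed tongue map equals the uninterrupted one", {
  p <- tiny_params()
  ck <- withr::local_tempfile(fileext = ".csv")
  S_grid <- c(0, 0.2); f_grid <- c(10, 25)
  # partial run: simulate an interruption by checkpointing a 2-cell prefix
  partial <- arnold_tongue(p, tc_state("task"), S_grid = S_grid[1],
                           f_grid = f_grid, duration_ms = 1200, seed = 3,
                           checkpoint = ck)
  # resumed full run reuses the checkpointed cells
  full_resumed <- arnold_tongue(p, tc_state("task"), S_grid = S_grid,
                                f_grid = f_grid, duration_ms = 1200, seed = 3,
                                checkpoint = ck)
  full_fresh <- arnold_tongue(p, tc_state("task"), S_grid = S_grid,
                              f_grid = f_grid, duration_ms = 1200, seed = 3)
  expect_true(all(!full_resumed$map$failed))
  expect_equal(full_resumed$map$peak_frequency, full_fresh$map$peak_frequency)
  expect_equal(full_resumed$map$entrained, full_fresh$map$entrained)
})

test_that("phase experiment warns at very low trial counts but runs", {
  p <- tiny_params()
  expect_warning(
    ph <- phase_experiment(p, tc_state("task"), n_trials = 2, seed = 1,
                           duration_ms = 700, n_shuffles = 20),
    "fewer than 20")
  expect_s3_class(ph, "tc_phase")
  expect_equal(ph$n_trials, 2)
})

test_that("sweep failures are recorded, not silently dropped", {
  p <- tc_params_small()
  # a duration shorter than one PSD window makes the analysis fail
  expect_warning(
    sw <- drive_sweep(p, d_lgn_values = 1e-4, seeds = 1L, duration_ms = 600,
                      corr_neurons = 0),
    "failed")
  expect_true(all(sw$failed))
  expect_equal(nrow(sw), 1)
})

test_that("run_all produces a manifest covering every experiment", {
  p <- tiny_params()
  out <- withr::local_tempdir()
  manifest <- suppressWarnings(run_all(out, preset = "smoke", seed = 1,
                                       params = p))
  expect_true(manifest$ok)
  expect_setequal(names(manifest$status),
                  c("rest_psd", "task_stim_psd", "drive_sham", "drive_stim",
                    "freq_sweep", "tongue", "phase", "sr"))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(file.exists(file.path(out, "tongue_rest.csv")))
  expect_true(file.exists(file.path(out, "mi_curve_stim.csv")))
  # provenance: config hash present and stable format
  expect_match(manifest$config_hash, "^[a-f0-9]{32}$")
})

test_that("tidiers return well-formed tibbles", {
  p <- tiny_params()
  sim <- tc_simulate(p, tc_state("rest"), duration_ms = 1200, seed = 1)
  td <- tidy(sim)
  expect_true(all(c("time_ms", "population", "value", "signal") %in% names(td)))
  g <- glance(sim)
  expect_equal(g$seed, 1)
  psd <- eeg_psd(sim)
  expect_equal(names(tidy(psd)), c("frequency", "power"))
  expect_true("peak_frequency" %in% names(glance(psd)))
  net <- build_network(p, 1)
  expect_gt(nrow(tidy(net)), 0)
  expect_equal(glance(net)$n_neurons, 70)
})

test_that("simulation and spectral results round-trip to disk", {
  p <- tiny_params()
  sim <- tc_simulate(p, tc_state("rest"), duration_ms = 1200, seed = 2)
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  eeg <- utils::read.csv(file.path(d, "eeg.csv"))
  expect_equal(nrow(eeg), length(sim$time))
  expect_equal(eeg$eeg, sim$eeg, tolerance = 1e-12)
  p2 <- load_parameters(file.path(d, "params.yaml"))
  expect_equal(p2$w[["e_e"]], p$w[["e_e"]])
  psd <- eeg_psd(sim)
  write_psd(psd, file.path(d, "psd"))
  meta <- jsonlite::read_json(file.path(d, "psd.json"))
  expect_equal(meta$peak_frequency, psd$peak_frequency)
})
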