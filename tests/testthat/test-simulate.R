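test_that("compiled and reference integrators agree draw-for-draw", {
  p <- tiny_params()
  s_cpp <- tc_simulate(p, tc_state("rest"), duration_ms = 200, seed = 3,
                       burn_in_ms = 0)
  s_r <- tc_simulate(p, tc_state("rest"), duration_ms = 200, seed = 3,
                     burn_in_ms = 0, engine = "r")
  expect_identical(s_cpp$raster, s_r$raster)    # spike path bit-identical
  expect_equal(s_cpp$eeg, s_r$eeg, tolerance = 1e-12)
  expect_equal(s_cpp$rates, s_r$rates, tolerance = 1e-12)
})

test_that("identical seed and configuration reproduce the run bit-exactly", {
  p <- tiny_params()
  s1 <- tc_simulate(p, tc_state("task"), tc_stimulus(0.1, 11),
                    duration_ms = 300, seed = 5)
  s2 <- tc_simulate(p, tc_state("task"), tc_stimulus(0.1, 11),
                    duration_ms = 300, seed = 5)
  expect_identical(s1$eeg, s2$eeg)
  expect_identical(s1$raster, s2$raster)
  expect_identical(s1$rates, s2$rates)
})

test_that("uncoupled noise-free dynamics match the linear ODE closed form", {
  # all weights zero, no noise, no adaptation: u relaxes as exp(-alpha t);
  # a fine step keeps the Euler discretization error below the tolerance
  w0 <- setNames(rep(0, 10), names(tc_params()$w))
  p <- tiny_params(w = as.list(w0), D = c(e = 0, i = 0, lgn = 0, rtn = 0),
                   b = 0, I = c(e = 0, i = 0, lgn = 0, rtn = 0),
                   init_jitter = 0, dt = 1e-4)
  net <- build_network(p, seed = 1)
  st <- tc_init_state(net, p, u0 = rep(1, 70))
  nst <- 10000  # 1 ms
  for (k in seq_len(nst)) st <- tc_step(st, net, p, stim_value = 0, d_lgn = 0)
  t_end <- nst * p$dt
  alpha <- p$alpha[rep(c("e", "i", "lgn", "rtn"), net$sizes)]
  expected <- exp(-alpha * t_end)
  expect_lt(max(abs(st$u - expected) / expected), 1e-3)
})

test_that("constant bias drives u and the adaptation variable to the bias", {
  w0 <- setNames(rep(0, 10), names(tc_params()$w))
  p <- tiny_params(w = as.list(w0), D = c(e = 0, i = 0, lgn = 0, rtn = 0),
                   I = c(e = 0.07, i = 0.07, lgn = 0.07, rtn = 0.07),
                   init_jitter = 0)
  # fixed point of du = alpha(-u + b v + I), dv = a(-v + u):
  # v* = u*, u* = I / (1 - b)
  sim <- tc_simulate(p, tc_state("custom", d_lgn = 0), duration_ms = 4000,
                     seed = 1, record_u = 1:3, record_u_every = 100L)
  u_star <- 0.07 / (1 - p$b)
  expect_equal(unname(sim$u_rec[nrow(sim$u_rec), ]), rep(u_star, 3),
               tolerance = 1e-2)
})

test_that("stimulation reaches cortical populations only", {
  # with zero weights the sub-cortical dynamics cannot see the stimulus
  w0 <- setNames(rep(0, 10), names(tc_params()$w))
  p <- tiny_params(w = as.list(w0))
  sham <- tc_simulate(p, tc_state("rest"), tc_stimulus(0, 11),
                      duration_ms = 300, seed = 8)
  stim <- tc_simulate(p, tc_state("rest"), tc_stimulus(0.5, 11),
                      duration_ms = 300, seed = 8)
  expect_identical(stim$rates[, "lgn"], sham$rates[, "lgn"])
  expect_identical(stim$rates[, "rtn"], sham$rates[, "rtn"])
  expect_false(identical(stim$rates[, "e"], sham$rates[, "e"]))
})

test_that("rates stay within [0, f_o] and spikes lie on the time grid", {
  p <- tiny_params()
  sim <- tc_simulate(p, tc_state("task"), duration_ms = 300, seed = 2)
  expect_true(all(sim$rates >= 0 & sim$rates <= p$f_o))
  expect_true(all(sim$raster$time %in% sim$time))
  expect_true(all(sim$raster$population %in% c("e", "i", "lgn", "rtn")))
})

test_that("EEG readout is the phi-weighted mean of cortical potentials", {
  u_e <- matrix(rnorm(50), 10, 5)
  u_i <- matrix(rnorm(20), 10, 2)
  # uniform weights: sum of the two population means
  expect_equal(simulate_eeg(u_e, u_i, rep(1, 5), rep(1, 2)),
               rowMeans(u_e) + rowMeans(u_i))
  # constant potentials give a constant trace for any weights
  a <- simulate_eeg(matrix(2, 10, 5), matrix(3, 10, 2), runif(5), runif(2))
  expect_equal(diff(range(a)), 0)
  expect_error(simulate_eeg(u_e[1:5, ], u_i), "lengths")
  expect_error(simulate_eeg(u_e, u_i, rep(1, 4), rep(1, 2)), "weight")
})

test_that("reweighting the EEG electrodes leaves the peak frequency alone", {
  p <- tc_params_small()
  sim <- tc_simulate(p, tc_state("rest"), duration_ms = 2000, seed = 1,
                     record_u = 1:250, record_u_every = 10L)
  keep <- seq_len(nrow(sim$u_rec)) * 10 * p$dt > sim$burn_in_ms
  u_e <- sim$u_rec[keep, 1:200]
  u_i <- sim$u_rec[keep, 201:250]
  fs <- sim$fs / 10
  set.seed(1)
  p1 <- compute_psd(simulate_eeg(u_e, u_i), fs)$peak_frequency
  set.seed(99)
  p2 <- compute_psd(simulate_eeg(u_e, u_i), fs)$peak_frequency
  expect_lte(abs(p1 - p2), 1)  # same rhythm, up to one frequency bin
})
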