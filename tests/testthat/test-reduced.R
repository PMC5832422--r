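test_that("effective gain has the stated closed form and monotonicity", {
  expect_equal(effective_gain(-1, 1 / (2 * pi), 0), -1)
  expect_equal(effective_gain(-1, 2 / (2 * pi), 0),
               effective_gain(-1, 1 / (2 * pi), 0) / sqrt(2))
  expect_gt(abs(effective_gain(-1, 0.1, 0)), abs(effective_gain(-1, 1, 0)))
  gam <- seq(0.05, 2, by = 0.05)
  expect_true(all(diff(abs(effective_gain(-1, gam, 0))) < 0))
  expect_error(effective_gain(-1, 0), "Gamma")
})

test_that("both Hopf-boundary routes agree and give the known critical gain", {
  hb1 <- hopf_boundary(T_ms = 90, condition = "characteristic")
  hb2 <- hopf_boundary(T_ms = 90, condition = "printed")
  expect_equal(hb1$Rc, hb2$Rc, tolerance = 1e-8)
  expect_equal(hb1$omega_c, hb2$omega_c, tolerance = 1e-8)
  # long-delay limit: the boundary approaches the delay-free threshold -1
  expect_equal(hopf_boundary(T_ms = 9000)$Rc, -1, tolerance = 1e-3)
  # slow adaptation barely moves the boundary
  hb3 <- hopf_boundary(T_ms = 90, b = 0.3, s = 10)
  expect_equal(hb3$Rc, hb1$Rc, tolerance = 0.01)
  expect_error(hopf_boundary(T_ms = -1), "T_ms")
})

test_that("DDE integration flips from decay to growth across the boundary", {
  hb <- hopf_boundary(T_ms = 90)
  amp_late <- function(R) {
    tr <- integrate_dde(R = R, linear = TRUE, T_ms = 90,
                        duration_ms = 4000, perturb = 1e-3)
    sd(tr$U[tr$time_ms > 3000])
  }
  expect_lt(amp_late(0.95 * hb$Rc), 1e-4)   # 5% below: decays
  expect_gt(amp_late(1.05 * hb$Rc), 1e-4)   # 5% above: grows/oscillates
  # bisection localizes the numerical boundary within 2% of the analytic one
  lo <- 0.9 * abs(hb$Rc); hi <- 1.1 * abs(hb$Rc)
  for (i in 1:7) {
    mid <- (lo + hi) / 2
    if (amp_late(-mid) > 1e-4) hi <- mid else lo <- mid
  }
  expect_lt(abs((lo + hi) / 2 - abs(hb$Rc)) / abs(hb$Rc), 0.02)
})

test_that("supercritical oscillation emerges at the predicted frequency", {
  hb <- hopf_boundary(T_ms = 90)
  tr <- integrate_dde(R = 1.08 * hb$Rc, linear = TRUE, T_ms = 90,
                      duration_ms = 6000, perturb = 1e-4)
  late <- tr$U[tr$time_ms > 3000]
  # period from zero crossings of the growing linear oscillation
  sgn <- sign(late - mean(late))
  crossings <- which(diff(sgn) > 0)
  period_ms <- mean(diff(crossings)) * diff(tr$time_ms[1:2])
  f_pred <- hb$freq_hz
  expect_lt(abs(1000 / period_ms - f_pred) / f_pred, 0.05)
})

test_that("noise variance sweeping through critical collapses the cycle", {
  g <- -3
  amp <- vapply(c(0.05, 0.4, 1.5), function(gam) {
    tr <- integrate_dde(g = g, Gamma = gam, T_ms = 90, duration_ms = 5000,
                        perturb = 0.05)
    sd(tr$U[tr$time_ms > 2500])
  }, numeric(1))
  # |effective gain| decreasing through Rc: oscillation then silence
  expect_gt(amp[1], 0.1)
  expect_gt(amp[2], 0.1)
  expect_lt(amp[3], 1e-3)
})

test_that("analytic resonance amplitude matches DDE steady state within 1%", {
  skip_if_not_installed("deSolve")
  R <- -0.8  # sub-critical
  T_ms <- 90
  for (f_hz in c(2, 5, 10, 30)) {
    an <- resonance_amplitude(f_hz, R = R, S = 1, T_ms = T_ms)$amplitude
    tr <- integrate_dde(R = R, linear = TRUE, T_ms = T_ms, S = 1,
                        f_hz = f_hz, duration_ms = 8000, perturb = 0)
    late <- tr$U[tr$time_ms > 6000]
    num <- (max(late) - min(late)) / 2
    expect_lt(abs(num - an) / an, 0.01)
  }
})

test_that("deSolve integration confirms the nonlinear integrator", {
  skip_if_not_installed("deSolve")
  g <- -3; Gamma <- 0.4; s <- 10; b <- 0; T_units <- 9
  u0 <- reduced_fixed_point(g, Gamma, b)
  fb <- function(x) (g / 2) * (1 + thalacor:::erf(x / sqrt(2 * Gamma)))
  rhs <- function(t, y, parms) {
    Ud <- if (t < T_units) u0 + 0.05 else deSolve::lagvalue(t - T_units, 1)
    list(c(-y[1] + b * y[2] + fb(Ud),
           (-y[2] + y[1]) / s))
  }
  times <- seq(0, 500, by = 0.01)
  ref <- deSolve::dede(y = c(u0 + 0.05, u0), times = times, func = rhs,
                       parms = NULL)
  own <- integrate_dde(g = g, Gamma = Gamma, b = b, s = s, T_ms = 90,
                       duration_ms = 5000, dt = 0.01, perturb = 0.05)
  # compare steady oscillation amplitude and period, not pointwise paths
  ref_late <- ref[times > 250, 2]
  own_late <- own$U[own$time_ms > 2500]
  expect_equal(sd(own_late), sd(ref_late), tolerance = 0.05)
  expect_equal(mean(own_late), mean(ref_late), tolerance = 0.05)
})

test_that("forced linear response is unforced-null and homogeneous of degree 1", {
  r1 <- resonance_amplitude(seq(1, 20, by = 1), R = -0.9, S = 1)
  r2 <- resonance_amplitude(seq(1, 20, by = 1), R = -0.9, S = 2)
  expect_equal(r2$amplitude, 2 * r1$amplitude)
  expect_equal(r2$A, 2 * r1$A)
  r0 <- resonance_amplitude(5, R = -0.9, S = 0)
  expect_equal(r0$amplitude, 0)
  expect_equal(c(r0$A, r0$B), c(0, 0))
})

test_that("rest and task resonance curves show the state-dependence signature", {
  cv <- rest_vs_task_curves(f_hz = seq(0.5, 40, by = 0.1))
  rest <- cv[cv$regime == "rest", ]
  task <- cv[cv$regime == "task", ]
  # resonant peak: rest exceeds task
  expect_gt(max(rest$amplitude), max(task$amplitude))
  f_res <- rest$f_hz[which.max(rest$amplitude)]
  # far off-resonance (twice the resonant frequency): task exceeds rest
  i_off <- which.min(abs(rest$f_hz - 2 * f_res))
  expect_gt(task$amplitude[i_off], rest$amplitude[i_off])
  # both responses vanish at high frequency (low-pass)
  expect_lt(rest$amplitude[nrow(rest)], 0.05 * max(rest$amplitude))
  expect_lt(task$amplitude[nrow(task)], 0.2 * max(task$amplitude))
  expect_error(rest_vs_task_curves(rest_R = -0.5, task_R = -0.9), "exceed")
})
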