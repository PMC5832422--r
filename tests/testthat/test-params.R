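test_that("defaults carry the canonical parameter set", {
  p <- tc_params()
  expect_equal(p$w[["e_e"]], 20.4)
  expect_equal(p$w[["i_e"]], -30.6)
  expect_equal(p$w[["lgn_e"]], 85)
  expect_equal(p$tau_th, 45)
  expect_equal(p$tau_rtn, 10)
  expect_equal(p$n_e, 800L)
  expect_equal(p$c, 0.2)
  expect_equal(p$dt, 0.1)
  expect_equal(p$beta, 150)
  expect_equal(p$h, 0.1)
  expect_equal(p$f_o, 0.2)
  expect_equal(unname(p$alpha), c(0.9, 1.3, 0.5, 0.5))
  expect_equal(unname(p$sigma2[c("e_e", "i_e")]), c(0.01, 0.25))
})

test_that("load_parameters honours overrides and boundaries", {
  expect_equal(load_parameters(NULL)$tau_th, 45)
  expect_equal(load_parameters(list(c = 1.0))$c, 1.0)  # all-to-all boundary
  expect_equal(load_parameters(list(w_e_e = 10))$w[["e_e"]], 10)
  expect_equal(load_parameters(list(sigma2_i_e = 0.5))$sigma2[["i_e"]], 0.5)
  expect_equal(load_parameters(list(D_lgn = 0.5))$D[["lgn"]], 0.5)
})

test_that("unknown keys and invalid values are rejected", {
  expect_error(load_parameters(list(nonsense = 1)), "unknown configuration key")
  expect_error(load_parameters(list(w_q_z = 1)), "unknown")
  expect_error(tc_params(c = 0), "probability")
  expect_error(tc_params(c = 1.5), "probability")
  expect_error(tc_params(dt = -0.1), "dt")
  expect_error(tc_params(f_o = 0), "f_o")
  expect_error(tc_params(n_e = -5L), "positive integers")
})

test_that("weight signs must match the source population", {
  expect_error(tc_params(w_i_e = 5), "i_e")       # inhibitory source positive
  expect_error(tc_params(w_rtn_lgn = 1), "rtn_lgn")
  expect_error(tc_params(w_e_e = -1), "e_e")      # excitatory source negative
  expect_silent(validate_params(tc_params(w_i_e = -10)))
})

test_that("configuration round-trips bit-exactly through YAML", {
  p <- tc_params(w_e_e = 20.4000001, D_lgn = 1 / 3, v = pi / 300)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_params(p, f)
  p2 <- load_parameters(f)
  expect_identical(unclass(p2)[order(names(p2))], unclass(p)[order(names(p))])
})

test_that("brain states map to the fixed thalamic drive levels", {
  expect_equal(tc_state("rest")$d_lgn, 1e-4)
  expect_equal(tc_state("task")$d_lgn, 1)
  expect_equal(tc_state("custom", d_lgn = 0.01)$d_lgn, 0.01)
  expect_error(tc_state("custom", d_lgn = -1), "d_lgn")
  expect_error(tc_state("custom"), "requires")
  expect_error(tc_state("rest", d_lgn = 0.5), "fixed")
  expect_identical(make_state("task")$d_lgn, 1)
})

test_that("stimulation targets cortex only and sham is encoded by S = 0", {
  st <- tc_stimulus(0.15, 11)
  expect_setequal(st$targets, c("e", "i"))
  expect_equal(tc_stimulus(0)$S, 0)
  expect_error(tc_stimulus(-0.1, 11), "S")
})
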