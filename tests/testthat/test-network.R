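test_that("firing rate is the saturating sigmoid with the table's constants", {
  p <- tc_params()
  expect_equal(firing_rate(p$h, p), p$f_o / 2)          # midpoint
  expect_equal(firing_rate(1e6, p), p$f_o)              # saturation
  expect_equal(firing_rate(0, p), 0.2 / (1 + exp(15)))  # closed form at u = 0
  u <- seq(-0.1, 0.25, by = 0.01)  # range where rates are representable
  expect_true(all(diff(firing_rate(u, p)) > 0))         # strictly increasing
  expect_true(all(firing_rate(u, p) > 0 & firing_rate(u, p) < p$f_o))
})

test_that("edge counts follow binomial sampling with probability c", {
  p <- tc_params(n_e = 100L, n_i = 10L, n_lgn = 10L, n_rtn = 10L)
  net <- build_network(p, seed = 11)
  n_ee <- sum(net$edges$projection == "e_e")
  mu <- 100 * 100 * p$c
  sig <- sqrt(100 * 100 * p$c * (1 - p$c))
  expect_lt(abs(n_ee - mu), 4 * sig)
  # only the ten anatomical projections appear
  expect_setequal(unique(net$edges$projection),
                  c("e_e", "e_i", "i_e", "i_i", "e_lgn", "e_rtn",
                    "lgn_e", "lgn_i", "lgn_rtn", "rtn_lgn"))
})

test_that("delays combine the fixed loop latency with conduction time", {
  p <- tiny_params()
  net <- build_network(p, seed = 2)
  ed <- net$edges
  pos <- net$positions
  # thalamo-cortical edges: latency 45 ms plus |dx|/v
  tc <- ed[ed$projection == "e_lgn", ]
  xs <- pos$x[pos$population == "e"][tc$src]
  xt <- pos$x[pos$population == "lgn"][tc$tgt]
  expect_equal(tc$delay_ms, abs(xt - xs) / p$v + 45)
  # a zero-distance thalamo-cortical edge has delay exactly 45 ms
  same <- which(abs(xt - xs) < 1e-12)
  if (length(same)) expect_equal(tc$delay_ms[same], rep(45, length(same)))
  # reticulo-thalamic latency is 10 ms; intracortical edges have none
  expect_true(all(ed$delay_ms[ed$projection == "rtn_lgn"] >= 10))
  ee <- ed[ed$projection == "e_e", ]
  expect_true(all(ee$delay_ms < p$omega / p$v + 1e-9))
  # all delays sit on the integration grid
  expect_equal(ed$delay_bins, as.integer(round(ed$delay_ms / p$dt)))
})

test_that("edge weights carry the source sign and the Gaussian profile", {
  p <- tiny_params(kernel_norm = "raw")
  net <- build_network(p, seed = 3)
  ed <- net$edges
  inh <- ed$from %in% c("i", "rtn")
  expect_true(all(ed$weight[inh] <= 0))
  expect_true(all(ed$weight[!inh] >= 0))
  # raw normalization: w0 / sqrt(2 pi sigma2) * exp(-dx^2 / (2 sigma2))
  ee <- ed[ed$projection == "e_e", ]
  xs <- net$positions$x[net$positions$population == "e"]
  dx <- xs[ee$tgt] - xs[ee$src]
  s2 <- p$sigma2[["e_e"]]
  expect_equal(ee$weight,
               p$w[["e_e"]] / sqrt(2 * pi * s2) * exp(-dx^2 / (2 * s2)))
})

test_that("expected kernel normalization preserves the summed input", {
  p <- tc_params(n_e = 400L, n_i = 100L, n_lgn = 100L, n_rtn = 100L,
                 kernel_norm = "expected")
  net <- build_network(p, seed = 7)
  ee <- net$edges[net$edges$projection == "lgn_e", ]
  # per-target summed weight / N_source concentrates around w0
  tot <- tapply(ee$weight, ee$tgt, sum) / p$n_lgn
  expect_lt(abs(mean(tot) - p$w[["lgn_e"]]) / p$w[["lgn_e"]], 0.05)
})

test_that("a zero-weight projection contributes no edges", {
  p <- tiny_params(w_lgn_e = 0)
  net <- build_network(p, seed = 4)
  expect_false("lgn_e" %in% net$edges$projection)
})

test_that("the sampled graph is reproducible from its seed", {
  p <- tiny_params()
  expect_identical(build_network(p, seed = 9)$edges,
                   build_network(p, seed = 9)$edges)
  expect_false(identical(build_network(p, seed = 9)$edges,
                         build_network(p, seed = 10)$edges))
})

test_that("spike generation is Bernoulli thinning with the right moments", {
  set.seed(42)
  dt <- 0.1
  rate <- 0.1  # per ms
  n <- 100000
  spikes <- replicate(20, sum(generate_spikes(rep(rate, n), dt)))
  mu <- n * rate * dt
  expect_lt(abs(mean(spikes) - mu), 4 * sqrt(mu / 20))
  # dispersion index near 1 (Poisson-like at small p)
  expect_lt(abs(var(spikes) / mean(spikes) - 1), 0.5)
  expect_equal(sum(generate_spikes(rep(0, 1000), dt)), 0)
  expect_error(generate_spikes(c(0.1, -0.1), dt), "negative rate")
})
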