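#' Simulate the thalamo-cortical network
#'
#' Builds the sampled network graph for `seed`, then integrates the
#' stochastic delayed dynamics by Euler-Maruyama at step `dt`: per
#' neuron `j` of population `n`,
#' `du = alpha_n * (-u + b*v + S_rec + I_n + stim) dt + alpha_n *
#' sqrt(2 D_n dt) * xi`, adaptation `dv = a * (-v + u) dt`, recurrent
#' input `S_rec` read from delayed synaptic traces, spikes drawn by
#' Bernoulli thinning of the rate `f(u)`, and traces updated as
#' `E <- E * exp(-dt/tau_m) + spike / tau_m`. The periodic stimulus
#' `S * sin(2 pi f_stim t / 1000 + phase)` drives cortical excitatory
#' and inhibitory neurons only. The LGN noise intensity is taken from
#' `state`; all other intensities from `params$D`.
#'
#' Initial membrane potentials are jittered uniformly above the bias
#' current (`u0 = I_n + U(0, init_jitter)`, `v0 = u0`, empty synaptic
#' history), which ignites the rest-state limit cycle during the
#' burn-in; the burn-in window is flagged in the result and excluded by
#' all trace accessors.
#'
#' Identical `seed` and configuration give bit-identical results; every
#' random draw (graph, EEG weights, initial state, noise, spikes) comes
#' from the single R RNG stream seeded once.
#'
#' @param params A `tc_params` object.
#' @param state A `tc_state` object (thalamic drive).
#' @param stim A `tc_stimulus` object.
#' @param duration_ms Analysis duration in ms (after burn-in).
#' @param seed Integer seed.
#' @param burn_in_ms Burn-in discarded from analyses (default 500 ms).
#' @param record_u Global neuron indices whose membrane potential is
#'   recorded every `record_u_every` steps (`NULL` for none).
#' @param record_u_every Subsampling stride (in steps) for `record_u`.
#' @param engine `"cpp"` (compiled, default) or `"r"` (pure-R reference
#'   integrator, identical RNG stream; for validation on tiny networks).
#' @return A `tc_sim` object with elements `time` (ms, full grid),
#'   `rates` (matrix, columns e/i/lgn/rtn, spikes per ms), `eeg`,
#'   `raster` (tibble: time, population, neuron), `u_rec`, `fs` (Hz),
#'   `burn_in_ms`, `network`, and the specs used.
#' @examples
#' \donttest{
#' sim <- tc_simulate(tc_params_small(), tc_state("rest"),
#'                    duration_ms = 1000, seed = 1)
#' head(eeg_trace(sim))
#' }
#' @export
tc_simulate <- function(params = tc_params(), state = tc_state("rest"),
                        stim = tc_stimulus(), duration_ms = 2000,
                        seed = 1L, burn_in_ms = 500,
                        record_u = NULL, record_u_every = 10L,
                        engine = c("cpp", "r")) {
  stopifnot(inherits(params, "tc_params"), inherits(state, "tc_state"),
            inherits(stim, "tc_stimulus"))
  engine <- match.arg(engine)
  if (duration_ms <= 0) abort("duration_ms must be > 0")
  net <- build_network(params, seed = seed)  # seeds the RNG stream
  flat <- .flatten_network(net)
  n_tot <- flat$n_tot
  sizes <- net$sizes
  phi <- runif(sizes[["e"]] + sizes[["i"]])
  pop_of <- rep(.populations, sizes)
  # ignition protocol: jitter the cortical potentials and start the
  # cortical adaptation variable below baseline. Through the
  # hyperpolarizing b*v term the low adaptation acts as a smooth
  # depolarizing ramp that decays over the adaptation timescale
  # (~100 ms), sustaining cortical firing long enough for the
  # thalamo-cortical loop to lock into the alpha limit cycle; a bare
  # millisecond-scale jitter flash frequently collapses into the
  # coexisting silent state. The ramp is confined to the burn-in.
  cortical <- pop_of %in% c("e", "i")
  jit <- runif(n_tot, 0, params$init_jitter)
  jit[!cortical] <- 0
  u0 <- params$I[pop_of] + jit
  v0 <- u0 - ifelse(cortical, params$init_adapt_offset, 0)
  D <- params$D
  D[["lgn"]] <- state$d_lgn
  n_steps <- as.integer(round((burn_in_ms + duration_ms) / params$dt))
  rec_idx <- if (is.null(record_u)) integer(0) else as.integer(record_u)

  core <- if (engine == "cpp") sim_core else .sim_core_r
  res <- core(n_steps, params$dt, as.integer(sizes),
              as.numeric(params$alpha[.populations]), params$a, params$b,
              params$tau_m, as.numeric(params$I[.populations]),
              as.numeric(D[.populations]), params$f_o, params$beta,
              params$h, flat$tgt, flat$src, flat$w, flat$dbin,
              as.numeric(u0), as.numeric(v0),
              stim$S, stim$f_stim, stim$phase, phi,
              as.integer(record_u_every), rec_idx)

  time <- seq_len(n_steps) * params$dt
  colnames(res$rates) <- .populations
  raster <- tibble::tibble(
    time = res$spike_step * params$dt,
    population = pop_of[res$spike_neuron],
    neuron = res$spike_neuron
  )
  structure(list(
    time = time, rates = res$rates, eeg = as.numeric(res$eeg),
    raster = raster, u_rec = res$u_rec, u_rec_idx = rec_idx,
    u_rec_every = record_u_every,
    fs = 1000 / params$dt, burn_in_ms = burn_in_ms,
    duration_ms = duration_ms, phi = phi,
    network = net, params = params, state = state, stim = stim,
    seed = seed
  ), class = "tc_sim")
}

#' @export
print.tc_sim <- function(x, ...) {
  cat(sprintf("<tc_sim> %s state, S=%g f=%g Hz, %g ms (+%g ms burn-in), seed %d\n",
              x$state$label, x$stim$S, x$stim$f_stim, x$duration_ms,
              x$burn_in_ms, x$seed))
  cat(sprintf("  %d neurons, %d spikes, fs = %g Hz\n",
              sum(x$network$sizes), nrow(x$raster), x$fs))
  invisible(x)
}

.post_burn <- function(sim) sim$time > sim$burn_in_ms

#' Post-burn-in EEG trace of a simulation
#' @param sim A `tc_sim` object.
#' @return Numeric vector sampled at `sim$fs` Hz.
#' @export
eeg_trace <- function(sim) sim$eeg[.post_burn(sim)]

#' Post-burn-in population mean-rate trace
#' @param sim A `tc_sim` object.
#' @param population One of `"e"`, `"i"`, `"lgn"`, `"rtn"`.
#' @return Numeric vector of population-mean rates (spikes per ms).
#' @export
rate_trace <- function(sim, population = "e") {
  stopifnot(population %in% .populations)
  sim$rates[.post_burn(sim), population]
}

#' Stimulation waveform evaluated on a simulation's analysis grid
#' @param sim A `tc_sim` object.
#' @return Numeric vector, the applied stimulus over the post-burn-in
#'   time grid.
#' @export
stim_trace <- function(sim) {
  t <- sim$time[.post_burn(sim)]
  sim$stim$S * sin(2 * pi * sim$stim$f_stim * t / 1000 + sim$stim$phase)
}

#' Simulated EEG from cortical membrane potentials
#'
#' `A(t) = mean_k(phi_e[k] * u_e[k](t)) + mean_k(phi_i[k] * u_i[k](t))`:
#' a weighted sum over somatic excitatory and inhibitory potentials with
#' fixed positive weights `phi` drawn uniformly on `[0, 1]`.
#'
#' @param u_e,u_i Matrices of membrane potentials, one column per
#'   neuron, rows = time points.
#' @param phi_e,phi_i Weight vectors; if `NULL`, drawn `U(0,1)` from the
#'   current RNG stream.
#' @return Numeric EEG trace.
#' @export
simulate_eeg <- function(u_e, u_i, phi_e = NULL, phi_i = NULL) {
  u_e <- as.matrix(u_e); u_i <- as.matrix(u_i)
  if (nrow(u_e) != nrow(u_i)) abort("trace lengths differ between e and i")
  if (is.null(phi_e)) phi_e <- runif(ncol(u_e))
  if (is.null(phi_i)) phi_i <- runif(ncol(u_i))
  if (length(phi_e) != ncol(u_e) || length(phi_i) != ncol(u_i))
    abort("weight length does not match neuron count")
  drop(u_e %*% phi_e) / ncol(u_e) + drop(u_i %*% phi_i) / ncol(u_i)
}

# Pure-R reference integrator, draw-for-draw identical to the compiled
# core (one rnorm per neuron then one runif per neuron, per step, in
# global neuron order). Used to validate the compiled path on tiny
# networks; O(steps * edges) in interpreted R.
.sim_core_r <- function(n_steps, dt, pop_sizes, alpha, a, b, tau_m, I, D,
                        f_o, beta, h, tgt, src, w, dbin, u0, v0,
                        stim_S, stim_f, stim_phase, phi,
                        record_u_every, record_u_idx) {
  n_tot <- sum(pop_sizes)
  pop_of <- rep(seq_along(pop_sizes), pop_sizes)
  H <- max(c(dbin, 0L)) + 1L
  u <- u0; v <- v0; E <- numeric(n_tot)
  hist <- matrix(0, n_tot, H)
  decay <- exp(-dt / tau_m)
  noise_sd <- alpha * sqrt(2 * D * dt)
  rates <- matrix(0, n_steps, length(pop_sizes))
  eeg <- numeric(n_steps)
  sp_step <- integer(0); sp_neuron <- integer(0)
  n_e <- pop_sizes[1]; n_i <- pop_sizes[2]
  n_rec <- length(record_u_idx)
  n_snap <- if (record_u_every > 0 && n_rec > 0)
    n_steps %/% record_u_every else 0L
  u_rec <- matrix(0, n_snap, n_rec)
  for (t0 in seq_len(n_steps) - 1L) {
    base <- t0 %% H
    S_in <- numeric(n_tot)
    if (length(src)) {
      sl <- base - dbin
      sl[sl < 0] <- sl[sl < 0] + H
      contrib <- w * hist[cbind(src + 1L, sl + 1L)]
      # rowsum adds within each target in data order, matching the
      # compiled core's accumulation order exactly
      acc <- rowsum(contrib, tgt, reorder = TRUE)
      S_in[as.integer(rownames(acc)) + 1L] <- acc[, 1]
    }
    xi <- rnorm(n_tot)
    stim <- stim_S * sin(2 * pi * stim_f * (t0 * dt) / 1000 + stim_phase)
    drive <- ifelse(pop_of <= 2, stim, 0)
    un <- u + alpha[pop_of] * dt * (-u + b * v + S_in + I[pop_of] + drive) +
      noise_sd[pop_of] * xi
    v <- v + a * dt * (-v + u)
    if (any(!is.finite(un))) {
      j <- which(!is.finite(un))[1]
      abort(sprintf("simulation diverged at t = %g ms (neuron %d)",
                    (t0 + 1) * dt, j))
    }
    u <- un
    r <- f_o / (1 + exp(-beta * (u - h)))
    spk <- as.integer(runif(n_tot) < r * dt)
    fired <- which(spk == 1L)
    sp_step <- c(sp_step, rep(t0 + 1L, length(fired)))
    sp_neuron <- c(sp_neuron, fired)
    E <- E * decay + spk / tau_m
    E[E < 1e-12] <- 0  # match the compiled core's subnormal flush
    hist[, ((t0 + 1L) %% H) + 1L] <- E
    rates[t0 + 1L, ] <- as.numeric(tapply(r, pop_of, mean))
    eeg[t0 + 1L] <- sum(phi[seq_len(n_e)] * u[seq_len(n_e)]) / n_e +
      sum(phi[n_e + seq_len(n_i)] * u[n_e + seq_len(n_i)]) / n_i
    if (n_snap > 0 && (t0 + 1L) %% record_u_every == 0) {
      row <- (t0 + 1L) %/% record_u_every
      if (row <= n_snap) u_rec[row, ] <- u[record_u_idx]
    }
  }
  list(rates = rates, eeg = eeg, spike_step = sp_step,
       spike_neuron = sp_neuron, u_rec = u_rec, u_final = u, v_final = v)
}

#' Advance a network state by one integration step (reference path)
#'
#' One Euler-Maruyama update of the full delayed stochastic system,
#' operating on an explicit `NetworkState` (as built by
#' [tc_init_state()]). This is the interpreted reference
#' implementation of the integrator's inner step; [tc_simulate()] runs
#' the same update in compiled code. Draws one normal and one uniform
#' variate per neuron from the current RNG stream.
#'
#' @param state A state list from [tc_init_state()] (fields `u`, `v`,
#'   `E`, `hist`, `t_step`).
#' @param network A `tc_network`.
#' @param params The `tc_params` used to build `network`.
#' @param stim_value Scalar stimulus (model voltage) applied to cortical
#'   neurons during this step.
#' @param d_lgn LGN noise intensity for this step.
#' @return The updated state, with `spikes` (0/1 per neuron) and `rate`
#'   fields describing the step just taken.
#' @export
tc_step <- function(state, network, params, stim_value = 0,
                    d_lgn = params$D[["lgn"]]) {
  flat <- .flatten_network(network)
  n_tot <- flat$n_tot
  pop_of <- rep(seq_along(.populations), network$sizes)
  H <- ncol(state$hist)
  if (H < flat$max_dbin + 1) abort("state history shorter than max delay")
  base <- state$t_step %% H
  S_in <- numeric(n_tot)
  if (length(flat$src)) {
    sl <- base - flat$dbin
    sl[sl < 0] <- sl[sl < 0] + H
    contrib <- flat$w * state$hist[cbind(flat$src + 1L, sl + 1L)]
    acc <- rowsum(contrib, flat$tgt, reorder = TRUE)
    S_in[as.integer(rownames(acc)) + 1L] <- acc[, 1]
  }
  alpha <- as.numeric(params$alpha[.populations])
  D <- as.numeric(params$D[.populations]); D[3] <- d_lgn
  I <- as.numeric(params$I[.populations])
  dt <- params$dt
  xi <- rnorm(n_tot)
  drive <- ifelse(pop_of <= 2, stim_value, 0)
  un <- state$u + alpha[pop_of] * dt *
    (-state$u + params$b * state$v + S_in + I[pop_of] + drive) +
    alpha[pop_of] * sqrt(2 * D[pop_of] * dt) * xi
  if (any(!is.finite(un)))
    abort(sprintf("simulation diverged at step %d (neuron %d)",
                  state$t_step + 1L, which(!is.finite(un))[1]))
  state$v <- state$v + params$a * dt * (-state$v + state$u)
  state$u <- un
  r <- firing_rate(state$u, params)
  spk <- generate_spikes(r, dt)
  state$E <- state$E * exp(-dt / params$tau_m) + spk / params$tau_m
  state$E[state$E < 1e-12] <- 0
  state$t_step <- state$t_step + 1L
  state$hist[, (state$t_step %% H) + 1L] <- state$E
  state$spikes <- spk
  state$rate <- r
  state
}

#' Initialize a NetworkState for the reference stepper
#'
#' @param network A `tc_network`.
#' @param params Its `tc_params`.
#' @param u0,v0 Optional initial potentials/adaptation (default: bias
#'   currents, no jitter).
#' @return A state list (`u`, `v`, `E`, `hist`, `t_step = 0`) whose
#'   history buffer spans the maximal delay.
#' @export
tc_init_state <- function(network, params, u0 = NULL, v0 = NULL) {
  flat <- .flatten_network(network)
  pop_of <- rep(.populations, network$sizes)
  if (is.null(u0)) u0 <- as.numeric(params$I[pop_of])
  if (is.null(v0)) v0 <- u0
  list(u = u0, v = v0, E = numeric(flat$n_tot),
       hist = matrix(0, flat$n_tot, flat$max_dbin + 1L), t_step = 0L)
}
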