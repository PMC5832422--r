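#' Saturating firing-rate function
#'
#' `f(u) = f_o / (1 + exp(-beta * (u - h)))`: the sigmoidal rate
#' (spikes per ms) at membrane potential `u`. Strictly increasing, with
#' range `(0, f_o)` and midpoint `f_o / 2` at `u = h`.
#'
#' @param u Membrane potential(s), any real.
#' @param params A `tc_params` object (uses `f_o`, `beta`, `h`).
#' @return Rate(s) in spikes per ms, same length as `u`.
#' @examples
#' firing_rate(0.1, tc_params()) # = f_o / 2
#' @export
firing_rate <- function(u, params = tc_params()) {
  params$f_o / (1 + exp(-params$beta * (u - params$h)))
}

#' Bernoulli spike generation from instantaneous rates
#'
#' One time bin of the non-homogeneous Poisson spiking process: each
#' neuron fires independently with probability `rate * dt` (thinning;
#' valid because `f_o * dt = 0.02 << 1`). Draws from the current R RNG
#' stream.
#'
#' @param rate Per-neuron rates in spikes per ms, each in `[0, f_o]`.
#' @param dt Bin width in ms.
#' @return Integer 0/1 vector of spike indicators.
#' @export
generate_spikes <- function(rate, dt) {
  if (any(rate < 0)) abort("negative rate passed to generate_spikes")
  as.integer(runif(length(rate)) < rate * dt)
}

# Even spacing of n neurons on [0, omega].
.positions <- function(n, omega) {
  if (n == 1) return(omega / 2)
  seq(0, omega, length.out = n)
}

#' Build the sampled network graph
#'
#' Samples the sparse, spatially topographic connectivity: for each of
#' the ten anatomical projections, each ordered (source, target) pair is
#' connected independently with probability `c`; a present edge carries
#' weight `w / (c * sqrt(2 * pi * sigma2)) * exp(-(xj - xk)^2 / (2 *
#' sigma2))` (kernel normalization `"expected"`, which makes the
#' expected summed input match the dense Gaussian kernel; `"raw"` omits
#' the `1/c` factor) and a conduction delay `|xj - xk| / v` plus the
#' fixed latency of the projection (45 ms between cortex and thalamus,
#' 10 ms between reticular and relay populations, 0 within cortex),
#' rounded to the integration grid.
#'
#' @param params A `tc_params` object.
#' @param seed Integer seed fixing the sampled graph.
#' @return A `tc_network` object: list with `positions` (tibble:
#'   population, index, x), `edges` (tibble: projection, from, to,
#'   src, tgt, weight, delay_ms, delay_bins) and `params`.
#' @examples
#' net <- build_network(tc_params_small(), seed = 1)
#' nrow(net$edges)
#' @export
build_network <- function(params = tc_params(), seed = 1L) {
  stopifnot(inherits(params, "tc_params"))
  set.seed(seed)
  sizes <- c(e = params$n_e, i = params$n_i,
             lgn = params$n_lgn, rtn = params$n_rtn)
  pos <- lapply(sizes, .positions, omega = params$omega)
  positions <- tibble::tibble(
    population = rep(names(sizes), sizes),
    index = unlist(lapply(sizes, seq_len), use.names = FALSE),
    x = unlist(pos, use.names = FALSE)
  )
  proj <- .projection_table()
  edges <- vector("list", nrow(proj))
  for (r in seq_len(nrow(proj))) {
    pr <- proj[r, ]
    w0 <- params$w[[pr$projection]]
    if (w0 == 0) next
    s2 <- params$sigma2[[pr$projection]]
    ns <- sizes[[pr$from]]; nt <- sizes[[pr$to]]
    conn <- matrix(runif(ns * nt) < params$c, nrow = ns, ncol = nt)
    idx <- which(conn, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    dx <- pos[[pr$to]][idx[, 2]] - pos[[pr$from]][idx[, 1]]
    if (params$kernel_norm == "expected") {
      # normalize by the realized kernel mass of each target so the
      # expected summed input (1/Ns) * sum_k W_jk over sampled edges is
      # exactly w0 for every neuron (no boundary truncation)
      g_dense <- exp(-outer(pos[[pr$from]], pos[[pr$to]], "-")^2 / (2 * s2))
      mass <- colSums(g_dense) / ns
      weight <- w0 * exp(-dx^2 / (2 * s2)) / (params$c * mass[idx[, 2]])
    } else {
      weight <- w0 / sqrt(2 * pi * s2) * exp(-dx^2 / (2 * s2))
    }
    delay_ms <- abs(dx) / params$v + pr$latency
    edges[[r]] <- tibble::tibble(
      projection = pr$projection, from = pr$from, to = pr$to,
      src = as.integer(idx[, 1]), tgt = as.integer(idx[, 2]),
      weight = weight, delay_ms = delay_ms,
      delay_bins = as.integer(round(delay_ms / params$dt))
    )
  }
  edges <- dplyr::bind_rows(edges)
  structure(list(positions = positions, edges = edges, params = params,
                 seed = seed, sizes = sizes),
            class = "tc_network")
}

#' @export
print.tc_network <- function(x, ...) {
  cat("<tc_network>", sum(x$sizes), "neurons,", nrow(x$edges), "edges\n")
  invisible(x)
}

# Flatten a tc_network into CSR-like arrays grouped by global target
# index, weights pre-divided by the source population size (the 1/N_n
# input normalization) for the integrator core.
.flatten_network <- function(net) {
  sizes <- net$sizes
  offset <- c(e = 0L, i = sizes[["e"]],
              lgn = sizes[["e"]] + sizes[["i"]],
              rtn = sizes[["e"]] + sizes[["i"]] + sizes[["lgn"]])
  n_tot <- sum(sizes)
  ed <- net$edges
  if (nrow(ed) == 0) {
    return(list(tgt = integer(0), src = integer(0),
                w = numeric(0), dbin = integer(0), n_tot = n_tot,
                offset = offset, max_dbin = 0L))
  }
  gsrc <- offset[ed$from] + ed$src - 1L   # 0-based global
  gtgt <- offset[ed$to] + ed$tgt - 1L
  w_eff <- ed$weight / sizes[ed$from]
  # (delay, source)-major order: the integrator reads each history
  # column sequentially, which dominates runtime
  ord <- order(ed$delay_bins, gsrc, gtgt)
  w_eff <- w_eff[ord]
  # round weights to float precision once, so the packed compiled core
  # and the double-precision R reference engine see identical values
  w_eff <- readBin(writeBin(w_eff, raw(), size = 4L),
                   what = "numeric", size = 4L, n = length(w_eff))
  list(tgt = as.integer(gtgt[ord]), src = as.integer(gsrc[ord]),
       w = w_eff, dbin = as.integer(ed$delay_bins[ord]),
       n_tot = n_tot, offset = offset, max_dbin = max(ed$delay_bins))
}
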