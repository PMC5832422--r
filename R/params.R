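#' @importFrom rlang abort warn .data
#' @importFrom stats fft median rnorm runif sd setNames quantile uniroot var cor
#' @importFrom utils modifyList head
NULL

# The ten anatomical projections of the circuit, in canonical order.
# Source and target populations, default synaptic strength w (signed),
# spatial spread sigma2, and the fixed inter-structure latency (ms).
.projection_table <- function() {
  tibble::tibble(
    projection = c("e_e", "e_i", "i_e", "i_i", "e_lgn", "e_rtn",
                   "lgn_e", "lgn_i", "lgn_rtn", "rtn_lgn"),
    from   = c("e", "e", "i", "i", "e", "e", "lgn", "lgn", "lgn", "rtn"),
    to     = c("e", "i", "e", "i", "lgn", "rtn", "e", "i", "rtn", "lgn"),
    w      = c(20.4, 30.6, -30.6, -20.4, 34, 34, 85, 85, 34, -34),
    sigma2 = c(0.01, 0.01, 0.25, 0.25, 0.01, 0.01, 0.25, 0.25, 0.25, 0.25),
    latency = c(0, 0, 0, 0, 45, 45, 45, 45, 10, 10)
  )
}

.populations <- c("e", "i", "lgn", "rtn")

.default_params <- function() {
  proj <- .projection_table()
  list(
    omega  = 1,
    n_e    = 800L,
    n_i    = 200L,
    n_lgn  = 200L,
    n_rtn  = 200L,
    beta   = 150,
    h      = 0.1,
    f_o    = 0.2,
    tau_m  = 1,
    alpha  = c(e = 0.9, i = 1.3, lgn = 0.5, rtn = 0.5),
    a      = 0.01,
    b      = -0.3,
    I      = c(e = 0, i = -0.3, lgn = -0.3, rtn = -0.3),
    tau_th = 45,
    tau_rtn = 10,
    v      = 0.01,
    c      = 0.2,
    dt     = 0.1,
    w      = setNames(proj$w, proj$projection),
    sigma2 = setNames(proj$sigma2, proj$projection),
    D      = c(e = 1e-3, i = 1e-3, lgn = 1e-4, rtn = 1e-3),
    kernel_norm = "raw",
    init_jitter = 0.2,
    init_adapt_offset = 0.5
  )
}

#' Model parameters for the thalamo-cortical network
#'
#' Constructs the complete parameter set of the four-population
#' thalamo-cortical circuit: population sizes, the saturating rate
#' function (gain `beta`, threshold `h`, ceiling `f_o`), membrane rate
#' constants `alpha`, spike-frequency adaptation (`a`, `b`), bias
#' currents `I`, synaptic time constant `tau_m`, conduction velocity `v`
#' (segment lengths per ms), connection probability `c`, loop latencies
#' `tau_th` (thalamus-cortex, ms) and `tau_rtn` (reticular-relay, ms),
#' per-projection synaptic strengths `w` and spatial spreads `sigma2`,
#' per-population noise intensities `D`, and the integration step `dt`
#' (ms). Time is in milliseconds throughout; voltage units are the
#' model's arbitrary units.
#'
#' The adaptation gain `b` enters the membrane equation as `+ b * v`
#' with default `b = -0.3`: negative values make the slow variable
#' hyperpolarizing (spike-frequency adaptation); positive values would
#' make it facilitating. `kernel_norm` selects the connectivity-kernel
#' normalization (`"raw"` or `"expected"`, see [build_network()]).
#' `init_jitter` and `init_adapt_offset` control the ignition protocol
#' of [tc_simulate()] (uniform jitter of initial cortical potentials
#' and the below-baseline start of the cortical adaptation variable);
#' both act only during the burn-in. The conduction velocity `v` is in
#' segment lengths per ms (default 0.01, i.e. 0.35 mm/ms across a
#' ~35 mm sheet mapped to the unit segment).
#'
#' @param ... Named overrides of any default. Vector-valued fields
#'   (`alpha`, `I`, `D`, `w`, `sigma2`) may be overridden wholesale or
#'   per element via names such as `w_e_e`, `sigma2_i_e`, `D_lgn`,
#'   `alpha_e`, `I_i`.
#' @param .validate Set `FALSE` to skip validation (internal use).
#'
#' @return An object of class `tc_params`: a named list of parameters.
#' @examples
#' p <- tc_params()
#' p$w[["e_e"]]
#' tc_params(c = 1.0)$c
#' @export
tc_params <- function(..., .validate = TRUE) {
  p <- .default_params()
  dots <- list(...)
  if (length(dots) && is.null(names(dots)) || any(names(dots) == "")) {
    if (length(dots)) abort("all parameter overrides must be named")
  }
  p <- .apply_overrides(p, dots)
  class(p) <- "tc_params"
  if (.validate) validate_params(p)
  p
}

.apply_overrides <- function(p, dots) {
  for (key in names(dots)) {
    val <- dots[[key]]
    if (key %in% names(p)) {
      if (is.list(val)) val <- unlist(val)
      if (!is.null(names(p[[key]])) && length(val) > 1 &&
          !is.null(names(val))) {
        bad <- setdiff(names(val), names(p[[key]]))
        if (length(bad)) abort(paste0("unknown element(s) in `", key, "`: ",
                                      paste(bad, collapse = ", ")))
        p[[key]][names(val)] <- val
      } else if (!is.null(names(p[[key]])) && length(val) > 1) {
        if (length(val) != length(p[[key]]))
          abort(paste0("`", key, "` must have length ", length(p[[key]])))
        p[[key]][] <- val
      } else if (!is.null(names(p[[key]])) && length(val) == 1 &&
                 is.null(names(val))) {
        p[[key]][] <- val
      } else {
        p[[key]] <- val
      }
    } else {
      # element-wise key such as w_e_e, sigma2_lgn_rtn, D_lgn, alpha_e, I_i
      hit <- FALSE
      for (field in c("w", "sigma2", "D", "alpha", "I")) {
        pre <- paste0(field, "_")
        if (startsWith(key, pre)) {
          el <- substring(key, nchar(pre) + 1)
          if (el %in% names(p[[field]])) {
            p[[field]][[el]] <- val
            hit <- TRUE
          } else {
            abort(paste0("unknown configuration key: ", key))
          }
          break
        }
      }
      if (!hit) abort(paste0("unknown configuration key: ", key))
    }
  }
  p
}

#' Validate a parameter set
#'
#' Checks positivity of sizes and rates, range of the connection
#' probability, non-negative delays, and that every projection weight
#' carries the sign of its source population (inhibitory sources `i` and
#' `rtn` have weights <= 0, excitatory sources >= 0).
#'
#' @param p A `tc_params` object.
#' @return `p`, invisibly, if valid; otherwise an error naming the
#'   offending field (for weights, the projection).
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "tc_params"))
  sizes <- c(p$n_e, p$n_i, p$n_lgn, p$n_rtn)
  if (any(sizes != as.integer(sizes)) || any(sizes <= 0))
    abort("population sizes must be positive integers")
  if (p$f_o <= 0) abort("f_o must be > 0")
  if (p$beta <= 0) abort("beta must be > 0")
  if (p$c <= 0 || p$c > 1) abort("connection probability c must be in (0, 1]")
  if (p$dt <= 0) abort("dt must be > 0")
  if (p$tau_m <= 0) abort("tau_m must be > 0")
  if (p$tau_th < 0 || p$tau_rtn < 0) abort("delays must be >= 0")
  if (p$v <= 0) abort("conduction velocity v must be > 0")
  if (any(p$alpha <= 0)) abort("membrane rate constants alpha must be > 0")
  if (any(p$D < 0)) abort("noise intensities D must be >= 0")
  if (!p$kernel_norm %in% c("expected", "raw"))
    abort("kernel_norm must be 'expected' or 'raw'")
  proj <- .projection_table()
  inhib <- proj$from %in% c("i", "rtn")
  wv <- p$w[proj$projection]
  bad <- proj$projection[(inhib & wv > 0) | (!inhib & wv < 0)]
  if (length(bad))
    abort(paste0("weight sign violates source-population sign rule for ",
                 "projection(s): ", paste(bad, collapse = ", ")))
  invisible(p)
}

#' Load parameters from a configuration source
#'
#' Reads a hierarchical YAML/JSON-style configuration (a file path or an
#' already-parsed named list) whose keys mirror the parameter names of
#' [tc_params()] (romanized, e.g. `w_e_e`, `sigma2_i_e`, `D_lgn`).
#' Absent keys take the model defaults; unknown keys are rejected.
#'
#' @param config_source Path to a YAML file, or a named list (possibly
#'   nested one level, e.g. `list(w = list(e_e = 20.4))`), or `NULL` for
#'   all defaults.
#' @return A validated `tc_params` object.
#' @examples
#' load_parameters(NULL)$tau_th
#' load_parameters(list(c = 1.0))$c
#' @export
load_parameters <- function(config_source = NULL) {
  if (is.null(config_source)) return(tc_params())
  if (is.character(config_source)) {
    if (!file.exists(config_source))
      abort(paste0("configuration file not found: ", config_source))
    config_source <- yaml::read_yaml(config_source)
  }
  if (!is.list(config_source)) abort("config must be a file path or a list")
  do.call(tc_params, config_source)
}

#' Write parameters to a YAML configuration file
#'
#' Serialization round-trips bit-exactly: `load_parameters(write_params(p,
#' f))` reproduces `p`.
#'
#' @param p A `tc_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "tc_params"))
  out <- unclass(p)
  for (field in c("alpha", "I", "D", "w", "sigma2")) out[[field]] <- as.list(out[[field]])
  # %.17g round-trips doubles exactly (yaml's precision argument caps lower)
  yaml::write_yaml(out, path,
                   handlers = list(numeric = function(x) {
                     if (length(x) == 1 && x == round(x) && abs(x) < 1e15)
                       return(x)
                     structure(sprintf("%.17g", x), class = "verbatim")
                   }))
  invisible(path)
}

#' @export
print.tc_params <- function(x, ...) {
  cat("<tc_params> thalamo-cortical model parameters\n")
  cat(sprintf("  populations: e=%d i=%d lgn=%d rtn=%d\n",
              x$n_e, x$n_i, x$n_lgn, x$n_rtn))
  cat(sprintf("  rate function: f_o=%g beta=%g h=%g; dt=%g ms\n",
              x$f_o, x$beta, x$h, x$dt))
  cat(sprintf("  delays: tau_th=%g ms, tau_rtn=%g ms, v=%g /ms; c=%g\n",
              x$tau_th, x$tau_rtn, x$v, x$c))
  invisible(x)
}

#' Brain-state specification (thalamic drive)
#'
#' The behavioural state of the circuit is set by the noise intensity
#' driving the thalamic relay (LGN) population: `"rest"` fixes
#' `D_lgn = 1e-4` (low drive, strong endogenous alpha), `"task"` fixes
#' `D_lgn = 1` (high drive, asynchronous firing), and `"custom"` takes
#' any non-negative intensity.
#'
#' @param label One of `"rest"`, `"task"`, `"custom"`.
#' @param d_lgn LGN noise intensity; required iff `label = "custom"`.
#' @return A `tc_state` object with fields `label` and `d_lgn`.
#' @examples
#' tc_state("rest")$d_lgn
#' tc_state("custom", d_lgn = 0.01)
#' @export
tc_state <- function(label = c("rest", "task", "custom"), d_lgn = NULL) {
  label <- match.arg(label)
  if (label == "rest") {
    if (!is.null(d_lgn)) abort("d_lgn is fixed at 1e-4 in the rest state")
    d_lgn <- 1e-4
  } else if (label == "task") {
    if (!is.null(d_lgn)) abort("d_lgn is fixed at 1 in the task state")
    d_lgn <- 1
  } else {
    if (is.null(d_lgn)) abort("custom state requires d_lgn")
    if (d_lgn < 0) abort("d_lgn must be >= 0")
  }
  structure(list(label = label, d_lgn = d_lgn), class = "tc_state")
}

#' @rdname tc_state
#' @export
make_state <- tc_state

#' Periodic cortical stimulation specification
#'
#' The stimulation waveform `S * sin(2 * pi * f_stim * t / 1000 + phase)`
#' (t in ms, `f_stim` in Hz) is applied identically to all cortical
#' excitatory and inhibitory neurons; sub-cortical populations never
#' receive stimulation. `S = 0` encodes sham.
#'
#' @param S Stimulation amplitude (model voltage units), `>= 0`.
#' @param f_stim Stimulation frequency in Hz.
#' @param phase Initial phase in radians.
#' @return A `tc_stimulus` object.
#' @examples
#' tc_stimulus(0.15, 11)
#' tc_stimulus(0) # sham
#' @export
tc_stimulus <- function(S = 0, f_stim = 0, phase = 0) {
  if (S < 0) abort("stimulation amplitude S must be >= 0")
  if (f_stim < 0) abort("stimulation frequency must be >= 0")
  structure(list(S = S, f_stim = f_stim, phase = phase,
                 targets = c("e", "i")),
            class = "tc_stimulus")
}

#' Scaled-down parameter preset
#'
#' Quarter-size network (200 excitatory, 50 of each other population)
#' with all densities, kernels and dynamics unchanged; expected synaptic
#' input per neuron is size-invariant under the kernel normalization, so
#' the mean-field dynamics match the full network with larger
#' finite-size fluctuations. Used for fast tests and smoke runs.
#'
#' @param ... Further overrides passed to [tc_params()].
#' @return A `tc_params` object.
#' @export
tc_params_small <- function(...) {
  tc_params(n_e = 200L, n_i = 50L, n_lgn = 50L, n_rtn = 50L, ...)
}
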