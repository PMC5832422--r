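# The reduced delayed-feedback oscillator runs in dimensionless time;
# one time unit corresponds to the effective relaxation time of the
# cortical population (~10 ms), so the thalamo-cortical loop delay
# T = 2 * 45 ms = 9 units.
.reduced_time_unit_ms <- 10

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Noise-linearized effective feedback gain
#'
#' `R_th = g / sqrt(2 * pi * Gamma) * exp(-u0^2 / (2 * Gamma))`: the
#' slope of the noise-smoothed threshold response at the fixed point
#' `u0`. For `u0 = 0`, `|R_th|` decreases as `1/sqrt(Gamma)`: noise
#' linearizes the response and lowers the loop gain.
#'
#' @param g Feedback gain of the threshold nonlinearity (`< 0`).
#' @param Gamma State-dependent noise variance (`> 0`).
#' @param u0 Fixed point of the mean dynamics.
#' @return Effective linear gain (same sign as `g`).
#' @examples
#' effective_gain(-1, 1 / (2 * pi)) # -1
#' @export
effective_gain <- function(g, Gamma, u0 = 0) {
  if (any(Gamma <= 0)) abort("Gamma must be > 0")
  g / sqrt(2 * pi * Gamma) * exp(-u0^2 / (2 * Gamma))
}

#' Hopf stability boundary of the linearized delayed oscillator
#'
#' Marginal stability of `dU/dt = -U + b/(1+s*lambda)-coupled adaptation
#' + R * U(t - T)`: setting the eigenvalue `lambda = i * omega` in the
#' characteristic equation and separating real and imaginary parts
#' yields, on the first-instability branch (`omega * T` in
#' `(pi/2, pi)`, the branch with the smallest critical `|R|`), the
#' critical negative gain `R_c` and frequency `omega_c`. In the
#' slow-adaptation limit (`b = 0`, the default, where the adaptation
#' term drops out of the characteristic equation) this reduces to the
#' classical delayed-feedback condition
#' `T * sqrt(R_c^2 - 1) = acos(1 / R_c)`, which is also available
#' directly as `condition = "printed"`.
#'
#' With the loop delay set to twice the thalamo-cortical latency
#' (`T_ms = 90`), the critical gain is about -1.05.
#'
#' @param T_ms Loop delay in ms (dimensionless delay
#'   `T = T_ms / time_unit_ms`).
#' @param b Adaptation coupling in the linearized equation (default 0:
#'   slow-adaptation limit).
#' @param s Adaptation slowness (dimensionless time units; only enters
#'   for `b != 0`).
#' @param condition `"characteristic"` (root of the full
#'   characteristic system) or `"printed"` (direct solution of the
#'   closed-form boundary condition; `b` must be 0).
#' @param time_unit_ms Duration of one dimensionless time unit (ms).
#' @return List with `Rc` (critical gain), `omega_c` (rad per time
#'   unit), `freq_hz` (oscillation frequency at onset, Hz), `T`
#'   (dimensionless), and the inputs.
#' @examples
#' hopf_boundary(T_ms = 90)$Rc # about -1.05
#' @export
hopf_boundary <- function(T_ms = 90, b = 0, s = 10,
                          condition = c("characteristic", "printed"),
                          time_unit_ms = .reduced_time_unit_ms) {
  condition <- match.arg(condition)
  if (T_ms <= 0) abort("T_ms must be > 0")
  T <- T_ms / time_unit_ms
  if (condition == "printed") {
    if (b != 0) abort("the printed boundary condition assumes b = 0")
    fn <- function(R) T * sqrt(R^2 - 1) - acos(1 / R)
    lo <- -1 - 1e-12
    hi <- -1 - 20 * pi / T  # far beyond the first branch
    if (fn(lo) * fn(hi) > 0)
      abort("no root bracketed on the first branch (printed condition)")
    Rc <- uniroot(fn, c(hi, lo), tol = 1e-12)$root
    omega_c <- sqrt(Rc^2 - 1)
  } else {
    # lambda = -1 + b/(1 + s*lambda) + R*exp(-lambda*T) at lambda = i*w:
    #   real: -1 + b/(1+s^2 w^2) + R cos(wT) = 0
    #   imag:  w + b s w/(1+s^2 w^2) + R sin(wT) = 0
    R_of <- function(w) (1 - b / (1 + s^2 * w^2)) / cos(w * T)
    fn <- function(w) {
      w + b * s * w / (1 + s^2 * w^2) + R_of(w) * sin(w * T)
    }
    eps <- 1e-9
    lo <- pi / (2 * T) + eps
    hi <- pi / T - eps
    if (fn(lo) * fn(hi) > 0)
      abort(paste0("no root on the first branch omega*T in (pi/2, pi); ",
                   "scanned [", signif(lo, 4), ", ", signif(hi, 4), "]"))
    omega_c <- uniroot(fn, c(lo, hi), tol = 1e-12)$root
    Rc <- R_of(omega_c)
  }
  list(Rc = Rc, omega_c = omega_c,
       freq_hz = omega_c / (2 * pi) * 1000 / time_unit_ms,
       T = T, T_ms = T_ms, b = b, s = s, condition = condition,
       time_unit_ms = time_unit_ms)
}

#' Forced-response amplitude of the linear delayed oscillator
#'
#' Substituting the entrained ansatz
#' `U = A * sin(f t) + B * cos(f t)` into
#' `dU/dt = a U + R U(t - T) + S sin(f t)` gives the exact linear
#' solution `A = -S P / (P^2 + Q^2)`, `B = -S Q / (P^2 + Q^2)` with
#' `P = a + R cos(fT)`, `Q = f + R sin(fT)`, and amplitude
#' `|U| = S / sqrt(P^2 + Q^2)`, linear in the forcing amplitude `S`.
#'
#' @param f_hz Forcing frequencies in Hz (vectorized).
#' @param R Effective feedback gain (negative).
#' @param S Forcing amplitude.
#' @param T_ms Loop delay in ms.
#' @param a Linear decay coefficient (default -1, the slow-adaptation
#'   limit).
#' @param time_unit_ms Duration of one dimensionless time unit (ms).
#' @return Tibble: `f_hz`, `f` (rad per unit), `A`, `B`, `amplitude`.
#' @export
resonance_amplitude <- function(f_hz, R, S = 1, T_ms = 90, a = -1,
                                time_unit_ms = .reduced_time_unit_ms) {
  T <- T_ms / time_unit_ms
  f <- 2 * pi * f_hz * time_unit_ms / 1000
  P <- a + R * cos(f * T)
  Q <- f + R * sin(f * T)
  den <- P^2 + Q^2
  if (any(den < 1e-14))
    abort("marginal stability: resonance pole (P = Q = 0) at a requested frequency")
  tibble::tibble(f_hz = f_hz, f = f, A = -S * P / den, B = -S * Q / den,
                 amplitude = S / sqrt(den))
}

#' Resonance curves above and below the Hopf threshold
#'
#' Computes the forced-response amplitude for a rest-like gain
#' (`|R| > |R_c|`, low noise: steep response, sharply tuned to the
#' intrinsic resonance) and a task-like gain (`|R| < |R_c|`, high
#' noise: linearized, reduced resonant peak but larger non-resonant
#' response).
#'
#' @param rest_R,task_R Effective gains; defaults place them 5% above
#'   and 20% below the critical gain for `T_ms` (a symmetric placement
#'   makes the two resonant peaks nearly equal and hides the
#'   state-dependence). `abs(rest_R)` must exceed `abs(task_R)`.
#' @param S Forcing amplitude.
#' @param f_hz Frequency grid (Hz).
#' @param T_ms Loop delay in ms.
#' @param ... Passed to [resonance_amplitude()].
#' @return Tibble with columns of [resonance_amplitude()] plus
#'   `regime` (`"rest"`/`"task"`) and `R`.
#' @export
rest_vs_task_curves <- function(rest_R = NULL, task_R = NULL, S = 1,
                                f_hz = seq(0.5, 30, by = 0.1),
                                T_ms = 90, ...) {
  if (is.null(rest_R) || is.null(task_R)) {
    Rc <- hopf_boundary(T_ms = T_ms)$Rc
    if (is.null(rest_R)) rest_R <- 1.05 * Rc
    if (is.null(task_R)) task_R <- 0.8 * Rc
  }
  if (abs(rest_R) <= abs(task_R))
    abort("|rest_R| must exceed |task_R| (noise reduces the gain)")
  dplyr::bind_rows(
    dplyr::mutate(resonance_amplitude(f_hz, rest_R, S, T_ms, ...),
                  regime = "rest", R = rest_R),
    dplyr::mutate(resonance_amplitude(f_hz, task_R, S, T_ms, ...),
                  regime = "task", R = task_R)
  )
}

#' Fixed point of the nonlinear reduced oscillator
#'
#' Solves `U (1 - b) = F_th(U)` with
#' `F_th(U) = (g/2) (1 + erf(U / sqrt(2 Gamma)))`.
#'
#' @inheritParams effective_gain
#' @param b Adaptation coupling.
#' @return The fixed point `u0`.
#' @export
reduced_fixed_point <- function(g, Gamma, b = 0) {
  fn <- function(U) U * (1 - b) - (g / 2) * (1 + erf(U / sqrt(2 * Gamma)))
  lo <- min(g / (1 - b) - 1, -1)
  uniroot(fn, c(lo, 1), tol = 1e-12)$root
}

#' Integrate the nonlinear (or linearized) reduced oscillator
#'
#' Euler-Maruyama integration of
#' `dU/dt = -U + b V + F(U(t - T)) + S sin(f t) + sqrt(2 D) xi(t)`,
#' `s dV/dt = -V + U`, with `F` either the threshold nonlinearity
#' `F_th(U) = (g/2)(1 + erf(U / sqrt(2 Gamma)))` (`linear = FALSE`) or
#' its linearization `R * U` about the fixed point (`linear = TRUE`,
#' with `R` supplied). History on `[-T, 0]` is held at the fixed point
#' (or `u_init`).
#'
#' @param g,Gamma Nonlinearity gain (`< 0`) and noise variance of the
#'   response function.
#' @param R Linear gain (used when `linear = TRUE`).
#' @param b,s Adaptation coupling and slowness.
#' @param T_ms Loop delay (ms).
#' @param S,f_hz Forcing amplitude and frequency.
#' @param D Intensity of additive white noise on `U` (0 for
#'   deterministic runs).
#' @param duration_ms Integration span (ms); must be much longer than
#'   the delay.
#' @param dt Time step in dimensionless units (default 0.01 = 0.1 ms).
#' @param u_init Initial/history value of `U` (default: fixed point,
#'   plus a small offset `perturb`).
#' @param perturb Initial perturbation added to the history endpoint.
#' @param seed Optional seed for the noise.
#' @param linear Use the linearized feedback `R * U(t - T)`.
#' @param time_unit_ms Duration of one dimensionless unit (ms).
#' @return Tibble: `time_ms`, `U`, `V`.
#' @export
integrate_dde <- function(g = -3, Gamma = 0.05, R = NULL, b = 0, s = 10,
                          T_ms = 90, S = 0, f_hz = 0, D = 0,
                          duration_ms = 3000, dt = 0.01,
                          u_init = NULL, perturb = 1e-3, seed = NULL,
                          linear = FALSE,
                          time_unit_ms = .reduced_time_unit_ms) {
  T <- T_ms / time_unit_ms
  if (duration_ms <= 2 * T_ms) abort("duration must greatly exceed the delay")
  if (!is.null(seed)) set.seed(seed)
  nd <- as.integer(round(T / dt))
  n <- as.integer(round(duration_ms / time_unit_ms / dt))
  if (linear) {
    if (is.null(R)) abort("linear integration requires R")
    u0 <- 0
    fb <- function(x) R * x
  } else {
    u0 <- reduced_fixed_point(g, Gamma, b)
    fb <- function(x) (g / 2) * (1 + erf(x / sqrt(2 * Gamma)))
  }
  if (is.null(u_init)) u_init <- u0
  buf <- rep(u_init, nd + n + 1)  # U(t) on the grid, with history prefix
  buf[nd + 1] <- u_init + perturb
  U <- u_init + perturb
  V <- u_init
  f <- 2 * pi * f_hz * time_unit_ms / 1000
  noise_sd <- sqrt(2 * D * dt)
  out_U <- numeric(n)
  out_V <- numeric(n)
  for (k in seq_len(n)) {
    t <- (k - 1) * dt
    Ud <- buf[nd + k - nd]  # U(t - T)
    dU <- -U + b * V + fb(Ud) + S * sin(f * t)
    U <- U + dt * dU + if (D > 0) noise_sd * rnorm(1) else 0
    V <- V + dt * (-V + U) / s
    if (!is.finite(U)) abort(sprintf("reduced model diverged at step %d", k))
    buf[nd + k + 1] <- U
    out_U[k] <- U
    out_V[k] <- V
  }
  tibble::tibble(time_ms = seq_len(n) * dt * time_unit_ms,
                 U = out_U, V = out_V)
}
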