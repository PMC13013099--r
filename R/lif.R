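#' LIF neuron parameters
#'
#' Parameter set for the discrete-time leaky integrate-and-fire neuron.
#' Dynamics are integrated by forward Euler with step `dt` (the stimulus
#' frame defines the clock, so `dt = 1` frame by default):
#' \deqn{v' = v + (dt/\tau_m)(v_{leak} - v + I)}
#' A spike is emitted when the membrane crosses the effective threshold,
#' after which the membrane is reset to `v_reset` (reset-to-value).
#'
#' @param v_leak leak (resting) voltage, volts. Default 0.
#' @param v_reset post-spike reset voltage, volts. Default 0.
#' @param v_th_base base firing threshold, volts. Default 1.
#' @param tau_m_base base membrane time constant, in frames. 4 is the
#'   feedforward-network default; recurrent networks use 16.
#' @param dt integration timestep, in frames.
#' @param tau_min lower clamp on the effective time constant (strictly
#'   positive) guarding against sign flips when a learned modulation drives
#'   the effective time constant negative.
#' @param beta slope of the SuperSpike surrogate derivative used in the
#'   backward pass, \eqn{1/(\beta|v - v_{th}| + 1)^2}.
#' @param tau_param `"direct"` modulates the time constant additively;
#'   `"inverse"` modulates the inverse time constant (leak rate) instead.
#' @return object of class `lif_params`.
#' @export
lif_params <- function(v_leak = 0, v_reset = 0, v_th_base = 1,
                       tau_m_base = 4, dt = 1, tau_min = 0.1,
                       beta = 100, tau_param = c("direct", "inverse")) {
  tau_param <- match.arg(tau_param)
  check_that(tau_m_base > 0, "tau_m_base must be > 0")
  check_that(dt > 0, "dt must be > 0")
  check_that(tau_min > 0, "tau_min must be > 0")
  check_that(beta > 0, "surrogate slope beta must be > 0")
  structure(list(v_leak = v_leak, v_reset = v_reset, v_th_base = v_th_base,
                 tau_m_base = tau_m_base, dt = dt, tau_min = tau_min,
                 beta = beta, tau_param = tau_param),
            class = "lif_params")
}

#' @export
print.lif_params <- function(x, ...) {
  cat("LIF parameters: v_th_base =", x$v_th_base,
      "V, tau_m_base =", x$tau_m_base, "frames, dt =", x$dt,
      "frames, v_leak =", x$v_leak, ", v_reset =", x$v_reset, "\n")
  invisible(x)
}

#' Context modulation of a neuron population
#'
#' A layer's neurons each own a learned projection `p_j` that converts the
#' global context scalar `c` into a unit-specific shift of either the firing
#' threshold or the membrane time constant. Exactly one mode is active per
#' layer.
#'
#' @param mode `"none"`, `"threshold"` or `"tau"`.
#' @param p numeric vector of per-unit learned projections (unused when
#'   `mode = "none"`).
#' @param c global context scalar, >= 0 (perturbation level or scaled dose).
#' @return object of class `context_mod`.
#' @export
context_mod <- function(mode = c("none", "threshold", "tau"),
                        p = numeric(0), c = 0) {
  mode <- match.arg(mode)
  check_that(is.numeric(c) && length(c) == 1 && c >= 0,
             "context scalar c must be a single value >= 0")
  if (mode != "none")
    check_that(length(p) >= 1 && all(is.finite(p)),
               "modulated layers need a finite projection vector p")
  structure(list(mode = mode, p = p, c = c), class = "context_mod")
}

#' Initialize per-unit projections
#'
#' Projections are initialized from a zero-mean normal with a small scale so
#' the unmodulated (c = 0) behavior is untouched at the start of training.
#'
#' @param n number of modulated units.
#' @param sd standard deviation of the initializer.
#' @return numeric vector of length `n`.
#' @export
init_projection <- function(n, sd = 0.1) stats::rnorm(n, mean = 0, sd = sd)

#' Effective firing threshold under context modulation
#'
#' \deqn{v_{th} = v_{th,base} + p c}
#' No clamping is applied: negative shifts are legal, and a unit whose
#' threshold falls below the reset voltage simply fires on every step.
#'
#' @param mod a [context_mod()] with `mode = "threshold"`.
#' @param params a [lif_params()].
#' @return per-unit threshold vector.
#' @export
effective_threshold <- function(mod, params) {
  check_that(inherits(mod, "context_mod") && mod$mode == "threshold",
             "effective_threshold requires a context_mod with mode 'threshold'")
  params$v_th_base + mod$p * mod$c
}

#' Effective membrane time constant under context modulation
#'
#' Direct parameterization: \eqn{\tau = \max(\tau_{base} + p c, \tau_{min})}.
#' Inverse parameterization (optional): the leak rate \eqn{1/\tau} is shifted
#' by \eqn{p c} and the result clamped so \eqn{\tau \ge \tau_{min}}.
#'
#' @inheritParams effective_threshold
#' @param mod a [context_mod()] with `mode = "tau"`.
#' @return per-unit time constants, in frames.
#' @export
effective_tau <- function(mod, params) {
  check_that(inherits(mod, "context_mod") && mod$mode == "tau",
             "effective_tau requires a context_mod with mode 'tau'")
  if (params$tau_param == "direct") {
    pmax(params$tau_m_base + mod$p * mod$c, params$tau_min)
  } else {
    rate <- 1 / params$tau_m_base + mod$p * mod$c
    1 / pmin(pmax(rate, 1 / 1e6), 1 / params$tau_min)
  }
}

#' Initialize a LIF (or leaky-integrator) state
#'
#' @param n number of units.
#' @param v initial membrane potential (recycled).
#' @return list with numeric vectors `v` (membrane) and `z` (last spike).
#' @export
lif_init_state <- function(n, v = 0) {
  list(v = rep_len(v, n), z = numeric(n))
}

# Resolve the per-unit (alpha = dt/tau, v_th) pair for a modulation setting.
lif_coefficients <- function(params, mod, n) {
  v_th <- rep_len(params$v_th_base, n)
  tau <- rep_len(params$tau_m_base, n)
  if (mod$mode == "threshold") v_th <- rep_len(effective_threshold(mod, params), n)
  if (mod$mode == "tau") tau <- rep_len(effective_tau(mod, params), n)
  list(alpha = params$dt / tau, v_th = v_th, tau = tau)
}

#' One discrete LIF timestep
#'
#' Forward-Euler membrane update, hard-Heaviside spike, reset-to-value:
#' \deqn{v' = v + (dt/\tau_{eff})(v_{leak} - v + I)}
#' \deqn{z' = \Theta(v' - v_{th,eff}), \qquad z' = 1 \Rightarrow v' := v_{reset}}
#' The forward pass is the hard nonlinearity; training code pairs it with the
#' SuperSpike surrogate derivative (see [surrogate_grad()]).
#'
#' @param state list with `v` and `z` as from [lif_init_state()].
#' @param input_current numeric vector of per-unit input currents.
#' @param params a [lif_params()].
#' @param mod a [context_mod()]; default unmodulated.
#' @return new state list with `v` and `z`.
#' @export
lif_step <- function(state, input_current, params, mod = context_mod()) {
  check_that(all(is.finite(input_current)), "input current must be finite")
  n <- length(state$v)
  co <- lif_coefficients(params, mod, n)
  v <- state$v + co$alpha * (params$v_leak - state$v + input_current)
  z <- as.numeric(v > co$v_th)
  v <- (1 - z) * v + z * params$v_reset
  list(v = v, z = z)
}

#' One leaky-integrator (non-spiking readout) timestep
#'
#' Same leak integration as [lif_step()] but never spikes and never resets;
#' used as the readout activation so spike evidence accumulates over a trial.
#'
#' @inheritParams lif_step
#' @param tau optional time constant override (e.g. `Inf` for a pure
#'   accumulator); defaults to `params$tau_m_base`.
#' @return new state list (`z` is kept at zero).
#' @export
li_step <- function(state, input_current, params, tau = NULL) {
  check_that(all(is.finite(input_current)), "input current must be finite")
  tau <- if (is.null(tau)) params$tau_m_base else tau
  if (is.infinite(tau)) {
    v <- state$v + input_current
  } else {
    a <- params$dt / tau
    v <- state$v + a * (params$v_leak - state$v + input_current)
  }
  list(v = v, z = numeric(length(v)))
}

#' SuperSpike surrogate derivative of the spike nonlinearity
#'
#' \deqn{\partial z/\partial v \approx 1 / (\beta |v - v_{th}| + 1)^2}
#'
#' @param v membrane potential (pre-reset).
#' @param v_th effective threshold.
#' @param beta surrogate slope.
#' @return surrogate derivative, same shape as `v`.
#' @export
surrogate_grad <- function(v, v_th, beta = 100) {
  1 / (beta * abs(v - v_th) + 1)^2
}

#' Frequency-current (FI) curve of a LIF unit
#'
#' Simulates one unit per constant input current level and returns the firing
#' rate (spikes per frame) over the simulated duration. Deterministic.
#'
#' @param params a [lif_params()].
#' @param mod a [context_mod()]; when modulated, `p` must be a single value
#'   (one characterized unit).
#' @param current_levels sorted numeric vector of constant input currents.
#' @param duration number of simulation steps (>= 100).
#' @return numeric vector of rates, one per current level, in spikes per
#'   frame (`count / (duration * dt)`).
#' @export
fi_curve <- function(params, mod = context_mod(), current_levels,
                     duration = 1000) {
  check_that(length(current_levels) >= 1, "current_levels must be non-empty")
  check_that(!is.unsorted(current_levels), "current_levels must be sorted")
  check_that(duration >= 100, "duration must be at least 100 steps")
  n <- length(current_levels)
  m <- mod
  if (m$mode != "none") {
    check_that(length(m$p) == 1, "fi_curve characterizes a single unit; p must be scalar")
    m$p <- rep(m$p, n)
  }
  st <- lif_init_state(n)
  count <- numeric(n)
  for (i in seq_len(duration)) {
    st <- lif_step(st, current_levels, params, m)
    count <- count + st$z
  }
  count / (duration * params$dt)
}
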