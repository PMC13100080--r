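#' Steady-state gate open fraction
#'
#' Sigmoidal voltage dependence of the equilibrium open fraction:
#' `0.5 * (1 + tanh((V - v_half) / dv))`.  A negative `dv` (h gate) flips
#' the curve into an inactivation characteristic.
#'
#' @param v membrane voltage (mV); vectorised.
#' @param gate a [gate_params()] object.
#' @return open fraction(s) in (0, 1).
#' @export
gate_steady_state <- function(v, gate) {
  stopifnot(inherits(gate, "gate_params"))
  0.5 * (1 + tanh((v - gate$v_half) / gate$dv))
}

#' Voltage-dependent gate relaxation time
#'
#' Bell-shaped voltage dependence
#' `tau0 + eps_tau * (1 - tanh^2((V - v_half) / dvt))`, ranging from `tau0`
#' far from `v_half` to `tau0 + eps_tau` at `v_half`.
#'
#' @inheritParams gate_steady_state
#' @return relaxation time(s) in ms.
#' @export
gate_time_constant <- function(v, gate) {
  stopifnot(inherits(gate, "gate_params"))
  gate$tau0 + gate$eps_tau * (1 - tanh((v - gate$v_half) / gate$dvt)^2)
}

#' Time derivative of the neuron state
#'
#' The membrane equation
#' `C dV/dt = gNa m^3 h (ENa - V) + gK n^4 (EK - V) + gL (EL - V) + I`
#' together with first-order gate relaxation
#' `dchi/dt = (chi_inf(V) - chi) / tau_chi(V)` for chi in m, h, n.
#'
#' @param state a [neuron_state()] object.
#' @param params a [neuron_params()] object.
#' @param current injected current (uA/cm^2).
#' @return named numeric vector `c(v, m, h, n)` of time derivatives.
#' @export
state_derivative <- function(state, params, current) {
  stopifnot(inherits(state, "neuron_state"), inherits(params, "neuron_params"))
  v <- state$v
  i_na <- params$g_na * state$m^3 * state$h * (params$e_na - v)
  i_k <- params$g_k * state$n^4 * (params$e_k - v)
  i_l <- params$g_l * (params$e_l - v)
  dv <- (i_na + i_k + i_l + current) / params$c_m
  dg <- vapply(c(m = "m", h = "h", n = "n"), function(nm) {
    g <- params$gates[[nm]]
    (gate_steady_state(v, g) - state[[nm]]) / gate_time_constant(v, g)
  }, numeric(1))
  c(v = dv, dg)
}

#' Resting fixed point at zero current
#'
#' Finds the resting membrane voltage by root-finding on the membrane
#' current balance with all gates at their steady-state curves, then
#' returns the full resting state.
#'
#' @param params a [neuron_params()] object.
#' @param interval voltage bracket (mV) searched for the root.
#' @return a [neuron_state()] at rest.
#' @export
resting_state <- function(params, interval = c(-90, -40)) {
  f <- function(v) {
    m <- gate_steady_state(v, params$gates$m)
    h <- gate_steady_state(v, params$gates$h)
    n <- gate_steady_state(v, params$gates$n)
    params$g_na * m^3 * h * (params$e_na - v) +
      params$g_k * n^4 * (params$e_k - v) +
      params$g_l * (params$e_l - v)
  }
  if (f(interval[1]) * f(interval[2]) > 0) {
    # heavily detuned surrogates can lose the hyperpolarised equilibrium
    # (depolarisation block); scan for the most hyperpolarised root
    hi <- max(params$e_na, params$e_k, params$e_l) - 1e-9
    grid <- seq(-120, hi, length.out = 400)
    fv <- vapply(grid, f, numeric(1))
    k <- which(fv[-1] * fv[-length(fv)] <= 0)[1]
    if (is.na(k)) stop("no resting fixed point found in [-120, ", round(hi),
                       "] mV")
    interval <- grid[c(k, k + 1)]
  }
  v <- uniroot(f, interval, tol = 1e-12)$root
  neuron_state(v,
               gate_steady_state(v, params$gates$m),
               gate_steady_state(v, params$gates$h),
               gate_steady_state(v, params$gates$n))
}

new_trajectory <- function(mat, dt, start_ms = 0, clamps = 0) {
  df <- data.frame(time_ms = start_ms + (seq_len(nrow(mat)) - 1) * dt,
                   V_mV = mat[, 1], m = mat[, 2], h = mat[, 3], n = mat[, 4])
  attr(df, "dt_ms") <- dt
  attr(df, "clamps") <- clamps
  class(df) <- c("hh_trajectory", "data.frame")
  df
}

#' Integrate the neuron over a current protocol
#'
#' Adaptive fifth-order Cash-Karp integration with embedded fourth-order
#' error control.  The current is held constant across each sampling
#' interval (zero-order hold), the step size adapts freely inside each
#' interval (capped at the sampling interval, floored at 1e-6 of it), and
#' the gate variables are clamped to `[0, 1]` after every accepted step.
#' The returned trajectory is sampled on the protocol grid.
#'
#' @param state0 initial [neuron_state()].
#' @param params a [neuron_params()] object.
#' @param protocol a [current_protocol()] object.
#' @param rtol,atol relative and absolute local error tolerances.
#' @param start_ms time stamp of the first sample.
#' @return an `hh_trajectory` data frame with columns
#'   `time_ms, V_mV, m, h, n` and attributes `dt_ms`, `clamps`.
#' @export
integrate_window <- function(state0, params, protocol, rtol = 1e-8,
                             atol = 1e-10, start_ms = 0) {
  stopifnot(inherits(state0, "neuron_state"),
            inherits(params, "neuron_params"),
            inherits(protocol, "current_protocol"))
  if (rtol <= 0 || atol <= 0) stop("tolerances must be > 0")
  res <- cpp_integrate(pack_neuron_state(state0), pack_neuron_params(params),
                       protocol$I, protocol$dt_ms, rtol, atol)
  if (res$status == 2)
    stop("integration aborted: state became non-finite (model too stiff ",
         "for the requested tolerance, or divergent parameters)")
  if (res$status == 1)
    warning("step size hit its floor; local error control was relaxed ",
            "on some steps")
  new_trajectory(res$trajectory, protocol$dt_ms, start_ms, res$clamps)
}

#' Generate a reference trajectory from rest
#'
#' Convenience wrapper around [integrate_window()]: starts from the resting
#' fixed point at zero current (found numerically) and integrates the full
#' protocol, returning the observable voltage together with the hidden gate
#' trajectories for later validation of gate-recovery claims.
#'
#' @inheritParams integrate_window
#' @return an `hh_trajectory` data frame.
#' @export
generate_reference <- function(params, protocol, rtol = 1e-8, atol = 1e-10) {
  integrate_window(resting_state(params), params, protocol,
                   rtol = rtol, atol = atol)
}

#' Count action potentials in a voltage trace
#'
#' Upward crossings of a threshold, used to check that generated protocols
#' elicit both sub- and supra-threshold responses.
#'
#' @param v voltage series (mV).
#' @param threshold crossing level (mV).
#' @return integer spike count.
#' @export
count_spikes <- function(v, threshold = 0) {
  above <- v > threshold
  sum(above[-1] & !above[-length(above)])
}
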