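#' Gate kinetics parameters
#'
#' Parameters of one ion-channel gate in the tanh parameterisation of the
#' Hodgkin-Huxley kinetics.  The steady-state open fraction is the sigmoid
#' `0.5 * (1 + tanh((V - v_half) / dv))` and the relaxation time is the
#' bell-shaped `tau0 + eps_tau * (1 - tanh^2((V - v_half) / dvt))`, so the
#' relaxation time runs from `tau0` far from `v_half` up to
#' `tau0 + eps_tau` at `v_half`.
#'
#' @param v_half half-activation voltage (mV).
#' @param dv sigmoid width (mV); a negative value encodes an inactivation
#'   gate (open fraction decreasing with voltage).
#' @param tau0 minimum relaxation time (ms), strictly positive.
#' @param eps_tau relaxation-time amplitude (ms), non-negative.
#' @param dvt width of the bell-shaped voltage dependence of the relaxation
#'   time (mV), strictly positive.
#' @return an object of class `gate_params`.
#' @export
gate_params <- function(v_half, dv, tau0, eps_tau, dvt) {
  stopifnot(is.numeric(v_half), is.numeric(dv), is.numeric(tau0),
            is.numeric(eps_tau), is.numeric(dvt))
  if (tau0 <= 0) stop("tau0 must be > 0")
  if (eps_tau < 0) stop("eps_tau must be >= 0")
  if (dv == 0) stop("dv must be non-zero")
  if (dvt <= 0) stop("dvt must be > 0")
  structure(list(v_half = v_half, dv = dv, tau0 = tau0,
                 eps_tau = eps_tau, dvt = dvt),
            class = "gate_params")
}

#' Hodgkin-Huxley neuron parameters
#'
#' Membrane and channel parameters of the conductance-based point neuron
#' with sodium (gates m, h), potassium (gate n) and leak currents.  Units
#' form a self-consistent point-neuron set: voltage in mV, time in ms,
#' capacitance in uF/cm^2, conductances in mS/cm^2, currents in uA/cm^2.
#'
#' @param c_m membrane capacitance, > 0.
#' @param g_na,g_k,g_l maximal conductances, >= 0.
#' @param e_na,e_k,e_l reversal potentials (mV).
#' @param gates named list with elements `m`, `h`, `n`, each a
#'   [gate_params()] object.
#' @return an object of class `neuron_params`.
#' @export
neuron_params <- function(c_m, g_na, g_k, g_l, e_na, e_k, e_l, gates) {
  if (c_m <= 0) stop("c_m must be > 0")
  if (g_na < 0 || g_k < 0 || g_l < 0) stop("conductances must be >= 0")
  if (!all(c("m", "h", "n") %in% names(gates)))
    stop("gates must contain m, h and n")
  for (g in gates[c("m", "h", "n")])
    if (!inherits(g, "gate_params")) stop("each gate must be a gate_params")
  structure(list(c_m = c_m, g_na = g_na, g_k = g_k, g_l = g_l,
                 e_na = e_na, e_k = e_k, e_l = e_l,
                 gates = gates[c("m", "h", "n")]),
            class = "neuron_params")
}

#' Default reference neuron
#'
#' Repository default parameter set: squid-axon-like magnitudes with tanh
#' gate kinetics, producing tonic spiking under step currents of a few
#' uA/cm^2 above rheobase.  All values are overridable through the config
#' file; none of the package's behavioural contracts depend on these exact
#' numbers.
#'
#' @return a [neuron_params()] object.
#' @export
default_neuron_params <- function() {
  neuron_params(
    c_m = 1, g_na = 120, g_k = 36, g_l = 0.3,
    e_na = 50, e_k = -77, e_l = -54.4,
    gates = list(
      m = gate_params(v_half = -40, dv = 15, tau0 = 0.1, eps_tau = 0.4,
                      dvt = 15),
      h = gate_params(v_half = -60, dv = -15, tau0 = 1, eps_tau = 7,
                      dvt = 15),
      n = gate_params(v_half = -55, dv = 30, tau0 = 1, eps_tau = 5,
                      dvt = 30)
    )
  )
}

#' Fractional model error
#'
#' Detunings applied to the surrogate model, each expressed as a fraction
#' of the reference value (0.1 = 10%): `eps_g` scales the sodium
#' conductance, `eps_v` the sodium activation threshold and `eps_tau` the
#' sodium activation relaxation-time curve.
#'
#' @param eps_g,eps_v,eps_tau fractional detunings.  `eps_g <= -1` is
#'   rejected (it would make the sodium conductance non-positive).
#' @return an object of class `model_error`.
#' @export
model_error <- function(eps_g = 0, eps_v = 0, eps_tau = 0) {
  if (eps_g <= -1) stop("eps_g <= -1 would give a non-physical conductance")
  structure(list(eps_g = eps_g, eps_v = eps_v, eps_tau = eps_tau),
            class = "model_error")
}

#' Detune a neuron model into a surrogate
#'
#' Applies fractional model error to the reference parameters:
#' `g_na <- g_na * (1 + eps_g)`, the m-gate half-activation
#' `v_half <- v_half * (1 + eps_v)`, and the whole m-gate relaxation-time
#' curve scaled by `(1 + eps_tau)` (both `tau0` and `eps_tau` of the m gate
#' are multiplied, so `tau_m(V)` is scaled at every voltage).  All other
#' fields are untouched.
#'
#' @param params a [neuron_params()] object.
#' @param error a [model_error()] object.
#' @return a detuned `neuron_params` copy.
#' @export
detune <- function(params, error) {
  stopifnot(inherits(params, "neuron_params"), inherits(error, "model_error"))
  if (error$eps_g <= -1) stop("eps_g <= -1 would give a non-physical conductance")
  out <- params
  out$g_na <- params$g_na * (1 + error$eps_g)
  out$gates$m$v_half <- params$gates$m$v_half * (1 + error$eps_v)
  out$gates$m$tau0 <- params$gates$m$tau0 * (1 + error$eps_tau)
  out$gates$m$eps_tau <- params$gates$m$eps_tau * (1 + error$eps_tau)
  out
}

#' Neuron state vector
#'
#' @param v membrane voltage (mV).
#' @param m,h,n gate open fractions in `[0, 1]`.
#' @return an object of class `neuron_state`.
#' @export
neuron_state <- function(v, m, h, n) {
  gates <- c(m, h, n)
  if (any(gates < 0 | gates > 1)) stop("gate fractions must lie in [0, 1]")
  structure(list(v = v, m = m, h = h, n = n), class = "neuron_state")
}

# flat numeric packing shared with the C++ core
pack_neuron_params <- function(p) {
  stopifnot(inherits(p, "neuron_params"))
  g <- function(x) c(x$v_half, x$dv, x$tau0, x$eps_tau, x$dvt)
  c(p$c_m, p$g_na, p$g_k, p$g_l, p$e_na, p$e_k, p$e_l,
    g(p$gates$m), g(p$gates$h), g(p$gates$n))
}

pack_neuron_state <- function(s) {
  stopifnot(inherits(s, "neuron_state"))
  c(s$v, s$m, s$h, s$n)
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("Hodgkin-Huxley neuron parameters\n")
  cat(sprintf("  C = %g uF/cm^2;  gNa = %g, gK = %g, gL = %g mS/cm^2\n",
              x$c_m, x$g_na, x$g_k, x$g_l))
  cat(sprintf("  ENa = %g, EK = %g, EL = %g mV\n", x$e_na, x$e_k, x$e_l))
  for (nm in c("m", "h", "n")) {
    g <- x$gates[[nm]]
    cat(sprintf("  %s: v_half = %g, dv = %g mV; tau in [%g, %g] ms\n",
                nm, g$v_half, g$dv, g$tau0, g$tau0 + g$eps_tau))
  }
  invisible(x)
}

#' @export
print.neuron_state <- function(x, ...) {
  cat(sprintf("neuron state: V = %.3f mV, m = %.4f, h = %.4f, n = %.4f\n",
              x$v, x$m, x$h, x$n))
  invisible(x)
}
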