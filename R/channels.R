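#' Gate rate-function specification
#'
#' Voltage-dependent opening (`alpha`) and closing (`beta`) rates of a
#' Hodgkin-Huxley gating particle are described by one of three classic
#' functional forms, each parameterised by an amplitude `A`, a voltage
#' `offset` (absolute membrane potential, V) and a voltage `scale` (V):
#'
#' * `linoid`:      `A * (offset - Vm) / (exp((offset - Vm)/scale) - 1)`,
#'   with the removable singularity at `Vm == offset` evaluated by its
#'   limit `A * scale`;
#' * `exponential`: `A * exp(-(Vm - offset)/scale)`;
#' * `sigmoid`:     `A / (exp((offset - Vm)/scale) + 1)`.
#'
#' @param form one of `"linoid"`, `"exponential"`, `"sigmoid"`.
#' @param A amplitude (1/s for exponential/sigmoid, 1/(s V) for linoid).
#' @param offset absolute voltage offset (V).
#' @param scale voltage scale (V), non-zero.
#' @return an object of class `rate_fn`.
#' @export
rate_fn <- function(form, A, offset, scale) {
  form <- match.arg(form, c("linoid", "exponential", "sigmoid"))
  stopifnot(is_number(A), is_number(offset), is_number(scale), scale != 0)
  structure(list(form = form, A = A, offset = offset, scale = scale),
            class = "rate_fn")
}

#' Evaluate a rate function at a membrane potential
#'
#' @param fn a [rate_fn()].
#' @param Vm membrane potential (V), may be a vector.
#' @return rate in 1/s (non-negative for the shipped kinetics).
#' @export
rate_eval <- function(fn, Vm) {
  stopifnot(inherits(fn, "rate_fn"), all(is.finite(Vm)))
  x <- fn$offset - Vm
  switch(fn$form,
    linoid = {
      r <- numeric(length(Vm))
      near <- abs(x / fn$scale) < 1e-9
      r[near] <- fn$A * fn$scale             # L'Hopital limit at the pole
      r[!near] <- fn$A * x[!near] / (exp(x[!near] / fn$scale) - 1)
      r
    },
    exponential = fn$A * exp(x / fn$scale),
    sigmoid = fn$A / (exp(x / fn$scale) + 1)
  )
}

#' Gating-particle specification
#'
#' @param name gate name (e.g. `"m"`, `"h"`, `"n"`).
#' @param power integer exponent of the gate in the channel conductance.
#' @param alpha,beta [rate_fn()] opening and closing rates.
#' @return an object of class `gate_spec`.
#' @export
gate_spec <- function(name, power, alpha, beta) {
  stopifnot(is.character(name), length(name) == 1L,
            is_number(power), power >= 0, power == round(power),
            inherits(alpha, "rate_fn"), inherits(beta, "rate_fn"))
  structure(list(name = name, power = as.integer(power),
                 alpha = alpha, beta = beta),
            class = "gate_spec")
}

#' Gate rate, steady state and time constant
#'
#' `gate_rate` evaluates the opening (`"alpha"`) or closing (`"beta"`) rate;
#' `gate_steady_state` returns `x_inf = alpha/(alpha + beta)` (in `[0, 1]`);
#' `gate_time_constant` returns `tau = 1/(alpha + beta)` (s, positive).
#'
#' @param gate a [gate_spec()].
#' @param which `"alpha"` or `"beta"`.
#' @param Vm membrane potential (V), vectorised.
#' @return numeric vector.
#' @export
gate_rate <- function(gate, which = c("alpha", "beta"), Vm) {
  which <- match.arg(which)
  rate_eval(gate[[which]], Vm)
}

#' @rdname gate_rate
#' @export
gate_steady_state <- function(gate, Vm) {
  a <- rate_eval(gate$alpha, Vm)
  b <- rate_eval(gate$beta, Vm)
  a / (a + b)
}

#' @rdname gate_rate
#' @export
gate_time_constant <- function(gate, Vm) {
  1 / (rate_eval(gate$alpha, Vm) + rate_eval(gate$beta, Vm))
}

#' Ionic current through a channel
#'
#' `I = GBAR * area * prod(gates^power) * (Vm - EREV)`; positive current is
#' outward.
#'
#' @param channel a channel node (from the model container) or a list with
#'   `params$GBAR` (S/m^2), `params$EREV` (V) and a `gates` list of
#'   [gate_spec()]s.
#' @param Vm membrane potential (V).
#' @param gates named numeric vector of gate states in `[0, 1]`, one per
#'   gate of the channel.
#' @param area membrane area of the owning compartment (m^2).
#' @return current in A.
#' @export
channel_current <- function(channel, Vm, gates, area) {
  stopifnot(all(gates >= 0 & gates <= 1))
  g <- channel$params$GBAR * area
  for (gs in channel$gates) g <- g * gates[[gs$name]]^gs$power
  g * (Vm - channel$params$EREV)
}

# the shipped squid-axon kinetics, used by the hodgkin-huxley.ndf library;
# offsets are absolute potentials with the resting point at -0.070 V
hh_gate_table <- function() {
  list(
    m = gate_spec("m", 3,
      alpha = rate_fn("linoid", 1e5, -0.045, 0.01),
      beta  = rate_fn("exponential", 4e3, -0.070, 0.018)),
    h = gate_spec("h", 1,
      alpha = rate_fn("exponential", 70, -0.070, 0.020),
      beta  = rate_fn("sigmoid", 1e3, -0.040, 0.01)),
    n = gate_spec("n", 4,
      alpha = rate_fn("linoid", 1e4, -0.060, 0.01),
      beta  = rate_fn("exponential", 125, -0.070, 0.080))
  )
}
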