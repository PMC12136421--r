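#' Gating-variable specification
#'
#' Describes one voltage-gated activation or inactivation variable of a
#' Hodgkin-Huxley channel by its Boltzmann steady state
#' \eqn{x_\infty(V) = \{1 + \exp[-(V-\theta)/\sigma]\}^{-1}} and a time-constant
#' rule. A `tau` of `NULL` marks the gate as instantaneous (set to
#' \eqn{x_\infty(V)} at every step); a single number is a voltage-independent
#' time constant in ms; a function of `V` gives a voltage-dependent \eqn{\tau(V)}.
#'
#' @param name Gate identifier (e.g. `"h"`, `"n"`).
#' @param theta Half-activation voltage \eqn{\theta}, mV.
#' @param sigma Slope factor \eqn{\sigma}, mV; positive gates open with
#'   depolarization, negative gates open with hyperpolarization. Must be nonzero.
#' @param tau Time-constant rule: `NULL`, a positive number (ms), or a
#'   `function(V)` returning ms.
#' @return An object of class `gate_spec`.
#' @export
gate_spec <- function(name, theta, sigma, tau = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(theta), is.numeric(sigma), sigma != 0)
  if (is.numeric(tau)) stopifnot(length(tau) == 1L, tau > 0)
  structure(list(name = name, theta = theta, sigma = sigma, tau = tau),
            class = "gate_spec")
}

#' Steady-state gate activation
#'
#' The Boltzmann steady state \eqn{x_\infty(V) = \{1+\exp[-(V-\theta)/\sigma]\}^{-1}},
#' shared by all voltage-dependent gates of the model.
#'
#' @param v Membrane voltage, mV (vectorized).
#' @param gate A [gate_spec()].
#' @return Activation in (0, 1).
#' @export
steady_state_gate <- function(v, gate) {
  1 / (1 + exp(-(v - gate$theta) / gate$sigma))
}

#' Gate time constant
#'
#' Evaluates the time-constant rule of a dynamic gate. Calling this for an
#' instantaneous gate (one with `tau = NULL`) is a contract violation and
#' errors.
#'
#' @inheritParams steady_state_gate
#' @return Time constant, ms (vectorized over `v`).
#' @export
gate_time_constant <- function(v, gate) {
  if (is.null(gate$tau))
    stop("gate '", gate$name, "' is instantaneous and has no time constant",
         call. = FALSE)
  if (is.function(gate$tau)) gate$tau(v) else rep_len(gate$tau, length(v))
}

#' Calcium-dependent gate steady states
#'
#' The fast calcium-activated potassium current uses
#' \eqn{d_\infty = [Ca]/([Ca]+a_c)} and the slow one
#' \eqn{q_\infty = [Ca]^4/([Ca]^4+a_q^4)}. Both are defined by continuity as 0
#' at zero calcium.
#'
#' @param ca Intracellular calcium concentration (model units), >= 0.
#' @param which `"d"` or `"q"`.
#' @param a_c,a_q Half-saturation constants.
#' @return Activation in [0, 1).
#' @export
calcium_gate <- function(ca, which = c("d", "q"), a_c = 6, a_q = 2) {
  which <- match.arg(which)
  stopifnot(all(ca >= 0))
  if (which == "d") ifelse(ca <= 0, 0, ca / (ca + a_c))
  else              ifelse(ca <= 0, 0, ca^4 / (ca^4 + a_q^4))
}

#' Ionic-channel specification
#'
#' One conductance-based current \eqn{I_j = g_j m^M h^N (V - E_j)}, optionally
#' multiplied by an instantaneous calcium gate (the `d` gate of the fast
#' Ca-activated K current; the `q` gate of the slow one is a dynamic state
#' whose steady state depends on calcium and is treated as the activation gate).
#'
#' @param name Channel identifier.
#' @param g Maximal conductance, mS/cm^2 (>= 0).
#' @param e Reversal potential, mV.
#' @param act [gate_spec()] of the activation gate, or `NULL`.
#' @param m_exp Activation exponent M (>= 0).
#' @param inact [gate_spec()] of the inactivation gate, or `NULL`.
#' @param n_exp Inactivation exponent N (>= 0).
#' @param ca_dependence `"none"`, `"d_gate"` or `"q_gate"`.
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(name, g, e, act = NULL, m_exp = 1L,
                         inact = NULL, n_exp = 0L,
                         ca_dependence = c("none", "d_gate", "q_gate")) {
  ca_dependence <- match.arg(ca_dependence)
  stopifnot(g >= 0, m_exp >= 0, n_exp >= 0)
  structure(list(name = name, g = g, e = e, act = act, m_exp = m_exp,
                 inact = inact, n_exp = n_exp, ca_dependence = ca_dependence),
            class = "channel_spec")
}

#' Instantaneous channel current
#'
#' Evaluates \eqn{I = g \cdot act^M \cdot inact^N \cdot (V - E)} for one channel
#' at one state. Gate values are taken from `gates` by gate name when the gate
#' is dynamic, and from \eqn{x_\infty(V)} when it is instantaneous. For
#' calcium-dependent channels the stated calcium gate multiplies the product.
#'
#' @param v Membrane voltage, mV.
#' @param spec A [channel_spec()].
#' @param gates Named numeric vector of dynamic gate values in \[0, 1\].
#' @param ca Calcium concentration (needed for `d_gate` channels).
#' @param a_c,a_q Calcium half-saturations.
#' @return Current density, uA/cm^2.
#' @export
channel_current <- function(v, spec, gates = numeric(), ca = 0,
                            a_c = 6, a_q = 2) {
  gv <- function(g) {
    if (is.null(g)) return(1)
    if (is.null(g$tau)) steady_state_gate(v, g) else unname(gates[[g$name]])
  }
  i <- spec$g * gv(spec$act)^spec$m_exp * gv(spec$inact)^spec$n_exp * (v - spec$e)
  if (spec$ca_dependence == "d_gate") i <- i * calcium_gate(ca, "d", a_c, a_q)
  i
}
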