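# Parameter bookkeeping for the CA1 pyramidal-cell model. The flat parameter
# vector order is shared with src/model_ca1.cpp (enum at the top of that file).

.ca1_param_order <- c(
  "c_m", "g_l", "e_l", "e_k", "e_na", "e_ca", "e_h",
  "g_nat", "g_nap", "g_kdr", "g_km", "g_ka", "g_hca", "g_fkca", "g_skca",
  "g_h", "g_ac", "n_comp",
  "nu", "tau_hca", "a_c", "a_q",
  "theta_m", "sigma_m", "theta_h", "sigma_h", "theta_ht", "sigma_ht",
  "theta_p", "sigma_p", "theta_n", "sigma_n", "theta_nt", "sigma_nt",
  "theta_z", "sigma_z", "tau_z", "theta_a", "sigma_a", "theta_b", "sigma_b",
  "tau_b",
  "theta_r", "sigma_r", "tau_r", "theta_c", "sigma_c", "tau_c", "tau_q",
  "theta_t", "sigma_t", "tau_t",
  "noise_d", "c_m_dend", "g_l_dend", "e_l_dend"
)

.ca1_defaults <- c(
  c_m = 1, g_l = 0.04, e_l = -70, e_k = -90, e_na = 55, e_ca = 120, e_h = -30,
  g_nat = 35, g_nap = 0.9, g_kdr = 5.8, g_km = 2.4, g_ka = 2.8, g_hca = 0.17,
  g_fkca = 9.05, g_skca = 2.8,
  g_h = 8.46, g_ac = 0.2, n_comp = 2,
  nu = 0.13, tau_hca = 13, a_c = 6, a_q = 2,
  theta_m = -30, sigma_m = 9.5, theta_h = -45, sigma_h = -7,
  theta_ht = -40.5, sigma_ht = -6,
  theta_p = -46, sigma_p = 6, theta_n = -35, sigma_n = 10,
  theta_nt = -27, sigma_nt = -15,
  theta_z = -39, sigma_z = 5, tau_z = 75, theta_a = -50, sigma_a = 20,
  theta_b = -80, sigma_b = -6, tau_b = 15,
  theta_r = -20, sigma_r = 19, tau_r = 1, theta_c = 30, sigma_c = 7,
  tau_c = 2, tau_q = 450,
  theta_t = -84, sigma_t = -10.2, tau_t = 50,
  noise_d = 9.6e-6, c_m_dend = 1, g_l_dend = 0.3, e_l_dend = -70
)

.ca1_profiles <- list(
  methods_default = c(),
  fig1_2 = c(g_nap = 0.3, g_kdr = 6, g_h = 0, n_comp = 1),
  fig3_7 = c(g_nap = 0.93, g_kdr = 5.86, g_h = 8.46, n_comp = 2)
)

#' Construct a CA1 pyramidal-cell model
#'
#' Builds the conductance-based CA1 pyramidal-cell model: a somatic compartment
#' with transient and persistent sodium (NaT, NaP), delayed-rectifier,
#' muscarinic and A-type potassium (KDR, KM, KA), high-threshold calcium (HCa)
#' and fast/slow calcium-activated potassium (fKCa, sKCa) currents, a single
#' intracellular calcium pool, and (when `n_comp = 2`) a passive dendritic
#' compartment carrying the hyperpolarization-activated current (h-current),
#' coupled to the soma by an ohmic axial conductance.
#'
#' Profiles bundle the conductance sets used for the different analyses:
#' * `"methods_default"`: the full published parameter list
#'   (g_NaP = 0.9, g_KDR = 5.8, two compartments).
#' * `"fig1_2"`: soma only, g_NaP = 0.3, g_KDR = 6, no h-current (step and
#'   single-sinusoid protocols).
#' * `"fig3_7"`: two compartments, g_NaP = 0.93, g_KDR = 5.86, g_h = 8.46
#'   (interleaved resonance, phase locking and quiet-interval protocols).
#'
#' @param profile One of `"methods_default"`, `"fig1_2"`, `"fig3_7"`.
#' @param ... Named parameter overrides (any name in `ca1_parameters()`), e.g.
#'   `g_nap = 0.35`. Conductances in mS/cm^2, voltages in mV, capacitance in
#'   uF/cm^2, time constants in ms.
#' @return An object of class `ca1_model`.
#' @examples
#' m <- ca1_model("fig1_2", g_nap = 0.35)
#' m
#' @export
ca1_model <- function(profile = c("methods_default", "fig1_2", "fig3_7"), ...) {
  profile <- match.arg(profile)
  par <- .ca1_defaults
  prof <- .ca1_profiles[[profile]]
  par[names(prof)] <- prof
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(par))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
      stop("unknown model parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    par[names(dots)] <- dots
  }
  stopifnot(par[["n_comp"]] %in% c(1, 2),
            par[["c_m"]] > 0, par[["g_l"]] >= 0, par[["g_ac"]] >= 0,
            par[["noise_d"]] >= 0, par[["sigma_b"]] != 0,
            par[["nu"]] >= 0, all(par[c("tau_hca", "a_c", "a_q")] > 0))
  structure(list(profile = profile, par = par[.ca1_param_order]),
            class = "ca1_model")
}

#' @export
print.ca1_model <- function(x, ...) {
  p <- x$par
  cat("<ca1_model> profile:", x$profile,
      sprintf("(%d compartment%s)\n", p[["n_comp"]],
              if (p[["n_comp"]] > 1) "s" else ""))
  g <- p[c("g_nap", "g_kdr", "g_nat", "g_km", "g_ka", "g_hca", "g_fkca",
           "g_skca", "g_h")]
  cat("  conductances (mS/cm^2):\n")
  print(round(g, 3))
  cat("  noise D:", format(p[["noise_d"]]), "\n")
  invisible(x)
}

#' Model parameter table
#'
#' @param model A [ca1_model()].
#' @return A tibble with one row per parameter (`name`, `value`).
#' @export
ca1_parameters <- function(model = ca1_model()) {
  tibble::tibble(name = names(model$par), value = unname(model$par))
}

# dynamic voltage-dependent gates and their tau rules
model_gates <- function(model) {
  p <- model$par
  sig <- function(v, th, sg) 1 / (1 + exp(-(v - th) / sg))
  g <- list(
    h = gate_spec("h", p[["theta_h"]], p[["sigma_h"]],
                  function(v) 0.1 + 0.75 * sig(v, p[["theta_ht"]], p[["sigma_ht"]])),
    n = gate_spec("n", p[["theta_n"]], p[["sigma_n"]],
                  function(v) 0.1 + 0.5 * sig(v, p[["theta_nt"]], p[["sigma_nt"]])),
    z = gate_spec("z", p[["theta_z"]], p[["sigma_z"]], p[["tau_z"]]),
    b = gate_spec("b", p[["theta_b"]], p[["sigma_b"]], p[["tau_b"]]),
    r = gate_spec("r", p[["theta_r"]], p[["sigma_r"]], p[["tau_r"]]),
    c = gate_spec("c", p[["theta_c"]], p[["sigma_c"]], p[["tau_c"]])
  )
  if (p[["n_comp"]] > 1)
    g$t <- gate_spec("t", p[["theta_t"]], p[["sigma_t"]], p[["tau_t"]])
  g
}

# somatic channel inventory as channel_spec objects (reference implementation)
model_channels <- function(model) {
  p <- model$par
  gs <- model_gates(model)
  m <- gate_spec("m", p[["theta_m"]], p[["sigma_m"]])
  pg <- gate_spec("p", p[["theta_p"]], p[["sigma_p"]])
  a <- gate_spec("a", p[["theta_a"]], p[["sigma_a"]])
  q <- gate_spec("q", 0, 1, p[["tau_q"]]) # steady state is calcium-driven
  list(
    nat  = channel_spec("nat",  p[["g_nat"]],  p[["e_na"]], m, 3, gs$h, 1),
    nap  = channel_spec("nap",  p[["g_nap"]],  p[["e_na"]], pg, 1),
    kdr  = channel_spec("kdr",  p[["g_kdr"]],  p[["e_k"]], gs$n, 4),
    km   = channel_spec("km",   p[["g_km"]],   p[["e_k"]], gs$z, 1),
    ka   = channel_spec("ka",   p[["g_ka"]],   p[["e_k"]], a, 3, gs$b, 1),
    hca  = channel_spec("hca",  p[["g_hca"]],  p[["e_ca"]], gs$r, 2),
    fkca = channel_spec("fkca", p[["g_fkca"]], p[["e_k"]], gs$c, 1,
                        ca_dependence = "d_gate"),
    skca = channel_spec("skca", p[["g_skca"]], p[["e_k"]], q, 1,
                        ca_dependence = "q_gate")
  )
}

#' Initial model state
#'
#' The resting initial condition used by the simulator: all compartments at
#' their leak reversal, dynamic voltage gates at their steady state
#' \eqn{x_\infty(E_L)}, calcium (and hence the q gate) at zero.
#'
#' @param model A [ca1_model()].
#' @return Named numeric state vector
#'   (`v_soma, h, n, z, b, r, c, q, ca, v_dend, t`).
#' @export
initial_state <- function(model) {
  p <- model$par
  gs <- model_gates(model)
  el <- p[["e_l"]]
  s <- c(v_soma = el,
         h = steady_state_gate(el, gs$h), n = steady_state_gate(el, gs$n),
         z = steady_state_gate(el, gs$z), b = steady_state_gate(el, gs$b),
         r = steady_state_gate(el, gs$r), c = steady_state_gate(el, gs$c),
         q = 0, ca = 0, v_dend = p[["e_l_dend"]], t = 0)
  if (p[["n_comp"]] > 1)
    s[["t"]] <- steady_state_gate(p[["e_l_dend"]], gs$t)
  s
}

#' Model state derivative (reference implementation)
#'
#' Pure-R evaluation of the full right-hand side: somatic membrane equation
#' \eqn{C dV/dt = -g_L(V-E_L) - \sum_j I_j - I_{ac} + I_{app}}, first-order
#' gate kinetics \eqn{dx/dt = (x_\infty(V)-x)/\tau_x(V)}, calcium dynamics
#' \eqn{d[Ca]/dt = -\nu I_{HCa} - [Ca]/\tau_{HCa}}, and for two-compartment
#' models the passive dendrite with h-current and the axial current
#' \eqn{I_{ac} = g_{ac}(V_i - V_{i+1})}. The compiled integrator uses an
#' equivalent hard-coded version; this one is built from [channel_spec()]
#' objects and serves as the readable reference (the two are tested against
#' each other and against independent arithmetic).
#'
#' @param model A [ca1_model()].
#' @param state Named state vector as from [initial_state()].
#' @param i_soma,i_dend Applied current density per compartment, uA/cm^2.
#' @return Named derivative vector (per ms).
#' @export
dstate_dt <- function(model, state, i_soma = 0, i_dend = 0) {
  p <- model$par
  chans <- model_channels(model)
  gs <- model_gates(model)
  v <- state[["v_soma"]]
  ca <- state[["ca"]]
  gate_vals <- state[c("h", "n", "z", "b", "r", "c", "q")]
  i_sum <- sum(vapply(chans, channel_current, numeric(1), v = v,
                      gates = gate_vals, ca = ca,
                      a_c = p[["a_c"]], a_q = p[["a_q"]]))
  i_ax <- if (p[["n_comp"]] > 1) p[["g_ac"]] * (v - state[["v_dend"]]) else 0
  d <- state * 0
  d[["v_soma"]] <- (-p[["g_l"]] * (v - p[["e_l"]]) - i_sum - i_ax + i_soma) /
    p[["c_m"]]
  for (nm in c("h", "n", "z", "b", "r", "c"))
    d[[nm]] <- (steady_state_gate(v, gs[[nm]]) - state[[nm]]) /
      gate_time_constant(v, gs[[nm]])
  d[["q"]] <- (calcium_gate(ca, "q", p[["a_c"]], p[["a_q"]]) - state[["q"]]) /
    p[["tau_q"]]
  i_hca <- channel_current(v, chans$hca, gate_vals, ca)
  d[["ca"]] <- -p[["nu"]] * i_hca - ca / p[["tau_hca"]]
  if (p[["n_comp"]] > 1) {
    vd <- state[["v_dend"]]
    i_h <- p[["g_h"]] * state[["t"]] * (vd - p[["e_h"]])
    d[["v_dend"]] <- (-p[["g_l_dend"]] * (vd - p[["e_l_dend"]]) - i_h -
                        p[["g_ac"]] * (vd - v) + i_dend) / p[["c_m_dend"]]
    d[["t"]] <- (steady_state_gate(vd, gs$t) - state[["t"]]) /
      gate_time_constant(vd, gs$t)
  }
  d
}
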