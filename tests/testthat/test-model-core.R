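test_that("steady-state gate follows the Boltzmann form", {
  g <- gate_spec("m", theta = -30, sigma = 9.5)
  expect_equal(steady_state_gate(-30, g), 0.5)
  expect_equal(steady_state_gate(1e4, g), 1)
  expect_equal(steady_state_gate(-1e4, g), 0)
  # persistent-sodium-style gate evaluated by independent scalar arithmetic
  gp <- gate_spec("p", theta = -35, sigma = 3)
  expect_equal(steady_state_gate(-26, gp), 1 / (1 + exp(-3)), tolerance = 1e-12)
  # monotone increasing for positive slope, decreasing for negative
  vv <- seq(-100, 40, 5)
  expect_true(all(diff(steady_state_gate(vv, g)) > 0))
  gh <- gate_spec("h", theta = -45, sigma = -7)
  expect_true(all(diff(steady_state_gate(vv, gh)) < 0))
})

test_that("calcium gates saturate correctly and are 0 at zero calcium", {
  expect_equal(calcium_gate(6, "d", a_c = 6), 0.5)
  expect_equal(calcium_gate(2, "q", a_q = 2), 0.5)
  expect_equal(calcium_gate(18, "d", a_c = 6), 0.75)
  expect_equal(calcium_gate(0, "d"), 0)
  expect_equal(calcium_gate(0, "q"), 0)
  expect_equal(calcium_gate(1e8, "d"), 1, tolerance = 1e-6)
  expect_equal(calcium_gate(1e4, "q"), 1, tolerance = 1e-6)
})

test_that("gate time constants match the model's rules", {
  gz <- gate_spec("z", -39, 5, 75)
  gq <- gate_spec("q", 0, 1, 450)
  for (v in c(-90, -60, -30, 0)) {
    expect_equal(gate_time_constant(v, gz), 75)
    expect_equal(gate_time_constant(v, gq), 450)
  }
  # voltage-dependent inactivation tau against the printed sigmoid form,
  # evaluated by independent scalar arithmetic at several voltages
  gs <- burstres:::model_gates(ca1_model())
  th_ht <- -40.5; sg_ht <- -6
  for (v in c(-80, -60, -45, -30, 0)) {
    expect_equal(gate_time_constant(v, gs$h),
                 0.1 + 0.75 / (1 + exp(-(v - th_ht) / sg_ht)),
                 tolerance = 1e-12)
    expect_equal(gate_time_constant(v, gs$n),
                 0.1 + 0.5 / (1 + exp(-(v + 27) / (-15))),
                 tolerance = 1e-12)
  }
  gm <- gate_spec("m", -30, 9.5) # instantaneous
  expect_error(gate_time_constant(-50, gm), "instantaneous")
})

test_that("channel currents follow I = g m^M h^N (V - E)", {
  n_gate <- gate_spec("n", -35, 10, 75)
  kdr <- channel_spec("kdr", g = 5.8, e = -90, act = n_gate, m_exp = 4)
  expect_equal(channel_current(-40, kdr, gates = c(n = 1)), 5.8 * 50)
  expect_equal(channel_current(-90, kdr, gates = c(n = 0.7)), 0)
  zero <- channel_spec("z", g = 0, e = -90, act = n_gate, m_exp = 4)
  expect_equal(channel_current(10, zero, gates = c(n = 0.5)), 0)
})

test_that("state derivative matches a hand-coded per-current oracle", {
  m <- ca1_model() # two-compartment default
  p <- m$par
  sig <- function(v, th, sg) 1 / (1 + exp(-(v - th) / sg))
  set.seed(11)
  for (k in 1:5) {
    st <- initial_state(m)
    st[["v_soma"]] <- runif(1, -90, 20)
    st[["v_dend"]] <- runif(1, -95, 0)
    st[c("h", "n", "z", "b", "r", "c", "q", "t")] <- runif(8)
    st[["ca"]] <- runif(1, 0, 10)
    i_s <- runif(1, -2, 3); i_d <- runif(1, -2, 3)
    v <- st[["v_soma"]]; ca <- st[["ca"]]
    # every current written out independently from the printed forms
    i_nat <- p[["g_nat"]] * sig(v, p[["theta_m"]], p[["sigma_m"]])^3 *
      st[["h"]] * (v - p[["e_na"]])
    i_nap <- p[["g_nap"]] * sig(v, p[["theta_p"]], p[["sigma_p"]]) *
      (v - p[["e_na"]])
    i_kdr <- p[["g_kdr"]] * st[["n"]]^4 * (v - p[["e_k"]])
    i_km <- p[["g_km"]] * st[["z"]] * (v - p[["e_k"]])
    i_ka <- p[["g_ka"]] * sig(v, p[["theta_a"]], p[["sigma_a"]])^3 *
      st[["b"]] * (v - p[["e_k"]])
    i_hca <- p[["g_hca"]] * st[["r"]]^2 * (v - p[["e_ca"]])
    i_fk <- p[["g_fkca"]] * (ca / (ca + p[["a_c"]])) * st[["c"]] *
      (v - p[["e_k"]])
    i_sk <- p[["g_skca"]] * st[["q"]] * (v - p[["e_k"]])
    i_ax <- p[["g_ac"]] * (v - st[["v_dend"]])
    dv_oracle <- (-p[["g_l"]] * (v - p[["e_l"]]) - i_nat - i_nap - i_kdr -
                    i_km - i_ka - i_hca - i_fk - i_sk - i_ax + i_s) /
      p[["c_m"]]
    d_r <- dstate_dt(m, st, i_s, i_d)
    d_cpp <- burstres:::dstate_ca1_cpp(unname(m$par), unname(st), i_s, i_d)
    expect_equal(d_r[["v_soma"]], dv_oracle, tolerance = 1e-12)
    expect_rel_equal(unname(d_r), d_cpp, tol = 1e-12)
    # calcium dynamics
    expect_equal(d_r[["ca"]],
                 -p[["nu"]] * i_hca - ca / p[["tau_hca"]], tolerance = 1e-12)
    # dendrite: leak + h-current + axial only
    vd <- st[["v_dend"]]
    i_h <- p[["g_h"]] * st[["t"]] * (vd - p[["e_h"]])
    expect_equal(d_r[["v_dend"]],
                 (-p[["g_l_dend"]] * (vd - p[["e_l_dend"]]) - i_h -
                    p[["g_ac"]] * (vd - v) + i_d) / p[["c_m_dend"]],
                 tolerance = 1e-12)
    # axial coupling conserves charge between the compartments
    expect_equal(p[["g_ac"]] * (v - vd) + p[["g_ac"]] * (vd - v), 0)
  }
})

test_that("leak equilibrium and axial symmetry are fixed points", {
  m <- passive_model()
  st <- initial_state(m)
  d <- dstate_dt(m, st, i_soma = 0)
  expect_equal(d[["v_soma"]], 0, tolerance = 1e-12)
  # two identical compartments at equal V carry no axial current
  m2 <- ca1_model(g_nat = 0, g_nap = 0, g_kdr = 0, g_km = 0, g_ka = 0,
                  g_hca = 0, g_fkca = 0, g_skca = 0, g_h = 0, noise_d = 0)
  st2 <- initial_state(m2)
  st2[["v_soma"]] <- st2[["v_dend"]] <- -70
  d2 <- dstate_dt(m2, st2, 0, 0)
  expect_equal(d2[["v_soma"]], 0, tolerance = 1e-12)
  expect_equal(d2[["v_dend"]], 0, tolerance = 1e-12)
})

test_that("gates relax to their steady state under constant voltage", {
  m <- ca1_model()
  gs <- burstres:::model_gates(m)
  v <- -52 # held constant
  for (nm in c("h", "n", "z", "b")) {
    g <- gs[[nm]]
    x <- 0.123
    dt <- 0.02
    tau_max <- gate_time_constant(v, g)
    for (i in seq_len(round(17 * tau_max / dt)))
      x <- x + dt * (steady_state_gate(v, g) - x) / gate_time_constant(v, g)
    expect_equal(x, steady_state_gate(v, g), tolerance = 1e-6)
  }
})

test_that("with nu = 0 calcium decays exponentially with tau_HCa", {
  m <- passive_model(nu = 0)
  init <- initial_state(m)
  init[["ca"]] <- 5
  res <- burstres:::sim_ca1_cpp(unname(m$par), numeric(50000), numeric(50000),
                                0.02, unname(init), FALSE)
  tt <- (seq_along(res$ca) - 1) * 0.02
  sel <- res$ca > 1e-6 & tt > 0
  tau_fit <- -1 / coef(stats::lm(log(res$ca[sel]) ~ tt[sel]))[[2]]
  expect_equal(tau_fit, 13, tolerance = 0.01)
})

test_that("model constructor validates inputs", {
  expect_error(ca1_model(nonsense = 1), "unknown model parameter")
  expect_error(ca1_model(c_m = -1))
  m <- ca1_model("fig1_2")
  expect_equal(m$par[["g_nap"]], 0.3)
  expect_equal(m$par[["n_comp"]], 1)
  expect_equal(ca1_model("fig3_7")$par[["g_h"]], 8.46)
  expect_equal(nrow(ca1_parameters()), length(m$par))
})
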