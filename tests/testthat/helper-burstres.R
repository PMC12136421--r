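# passive single-compartment model (all active conductances zero)
passive_model <- function(...) {
  ca1_model("fig1_2", g_nat = 0, g_nap = 0, g_kdr = 0, g_km = 0, g_ka = 0,
            g_hca = 0, g_fkca = 0, g_skca = 0, noise_d = 0, ...)
}

# short deterministic simulation of the default burst regime
quick_burst_trace <- function(duration = 1500, seed = 1) {
  simulate_ca1(ca1_model("fig1_2", g_nap = 0.35), stim_step(1),
               duration = duration, seed = seed)
}

expect_rel_equal <- function(x, y, tol = 1e-12) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-300)), tol)
}
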