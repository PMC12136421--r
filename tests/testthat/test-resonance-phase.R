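test_that("tuning curves: silent models give zero rates, ensembles average", {
  silent <- passive_model()
  tc <- tuning_curve(silent, freqs = c(10, 40), amplitude = 0.2,
                     duration = 600)
  expect_true(all(tc$rate_all == 0))
  # ensemble mean equals the mean of the matching single runs
  m <- ca1_model("fig1_2", g_nap = 0.35)
  tc2 <- tuning_curve(m, freqs = c(8, 40), amplitude = 1, n_runs = 2,
                      seed = 3, duration = 1200)
  ones <- lapply(c(3, 4), function(s)
    tuning_curve(m, freqs = c(8, 40), amplitude = 1, n_runs = 1, seed = s,
                 duration = 1200))
  expect_equal(tc2$rate_all, (ones[[1]]$rate_all + ones[[2]]$rate_all) / 2,
               tolerance = 1e-12)
  expect_true(all(c("sd_rate_all", "sd_cv") %in% names(tc2)))
})

test_that("resonance summary recovers argmax frequencies and amplitudes", {
  curve <- tibble::tibble(freq = seq(2, 100, 2))
  curve$rate_ss <- exp(-(curve$freq - 40)^2 / 200)
  curve$rate_bs <- 2 * exp(-(curve$freq - 10)^2 / 50)
  rs <- resonance_summary(curve)
  expect_equal(rs$f_ss, 40)
  expect_equal(rs$f_bs, 10)
  expect_equal(rs$delta_f, 30)
  expect_equal(rs$delta_a, 1 - 2)
  same <- curve; same$rate_bs <- same$rate_ss
  rs2 <- resonance_summary(same)
  expect_equal(rs2$delta_f, 0)
  expect_equal(rs2$delta_a, 0)
  # argmax ties break toward the lower frequency; all-zero curves are flagged
  flat <- curve; flat$rate_ss <- rep(1, nrow(flat)); flat$rate_bs <- 0
  rs3 <- resonance_summary(flat)
  expect_equal(rs3$f_ss, 2)
  expect_true(is.na(rs3$f_bs) && is.na(rs3$delta_f))
  expect_equal(tidy(rs)$value[tidy(rs)$quantity == "delta_f"], 30)
})

test_that("spike phases recover the phase of sinusoidal references", {
  fs <- 2000
  tt <- seq(0, 2000 - 0.5, 0.5)
  ref <- sin(2 * pi * 10 * tt / 1000)
  peaks <- 25 + 100 * (0:18)
  ph <- spike_phases(peaks, ref, fs, "theta")
  expect_lt(diff(range(ph[3:17])), 0.05) # equal away from filter edges
  troughs <- 75 + 100 * (0:18)
  ph2 <- spike_phases(troughs, ref, fs, "theta")
  d <- abs(ph[5:15] - ph2[5:15])
  expect_equal(pmin(d, 2 * pi - d), rep(pi, 11), tolerance = 0.05)
  # combined theta+gamma reference against an independent quadrature oracle
  ref2 <- sin(2 * pi * 10 * tt / 1000) + 2 * sin(2 * pi * 40 * tt / 1000)
  spikes <- seq(300, 1700, 37)
  ph_theta <- spike_phases(spikes, ref2, fs, "theta")
  ph_gamma <- spike_phases(spikes, ref2, fs, "gamma")
  # analytic phase of sin(wt) is wt - pi/2
  oracle <- function(f) {
    p <- (2 * pi * f * spikes / 1000 - pi / 2 + pi) %% (2 * pi) - pi
    p
  }
  dth <- abs(ph_theta - oracle(10)); dga <- abs(ph_gamma - oracle(40))
  expect_lt(max(pmin(dth, 2 * pi - dth)), 0.05)
  expect_lt(max(pmin(dga, 2 * pi - dga)), 0.05)
  expect_length(spike_phases(numeric(), ref, fs, "theta"), 0)
})

test_that("PLV and PLS follow their definitions", {
  expect_equal(plv(rep(1.3, 7)), 1)
  expect_equal(plv(seq(0, 2 * pi, length.out = 9)[-9]), 0, tolerance = 1e-12)
  expect_equal(plv(c(0, pi / 2)), sqrt(2) / 2, tolerance = 1e-12)
  expect_true(is.na(plv(numeric())))
  expect_equal(pls(1, 10), 1)
  expect_equal(pls(0, 10), -1 / 9)
  expect_equal(pls(0.5, 5), 0.0625)
  expect_true(is.na(pls(0.5, 1)))
  # properties: rotation invariance and the PLS bound
  set.seed(5)
  for (k in 1:10) {
    phases <- runif(sample(3:40, 1), -pi, pi)
    rot <- runif(1, -pi, pi)
    expect_equal(plv(phases), plv(phases + rot), tolerance = 1e-12)
    n <- length(phases)
    v <- plv(phases)
    expect_lte(pls(v, n), v^2 * n / (n - 1) + 1e-12)
    expect_lt(pls(v, n), 1) # equality only at perfect locking
  }
  expect_equal(pls(plv(rep(0.2, 6)), 6), 1)
})

test_that("group comparison computes pooled-s.d. Cohen's d and t-test", {
  same <- c(1, 2, 3)
  expect_equal(compare_groups(same, same)$cohens_d, 0)
  a <- c(0.5, 1.5); b <- c(-0.5, 0.5) # means 1 and 0, pooled sd sqrt(0.5)...
  d <- compare_groups(c(0, 2), c(-1, 1))$cohens_d
  expect_equal(d, (1 - 0) / sqrt(2), tolerance = 1e-12)
  cg <- compare_groups(c(1, 2, 3), c(2, 3, 4))
  expect_equal(cg$cohens_d, -1, tolerance = 1e-12)
  ref <- t.test(c(1, 2, 3), c(2, 3, 4), var.equal = TRUE)
  expect_equal(cg$p, ref$p.value)
  expect_equal(cg$t, unname(ref$statistic))
})

test_that("conductance sweeps decompose into independent single runs", {
  m <- ca1_model("fig1_2")
  sw <- conductance_sweep(m, "g_nap", c(0.2, 0.35), "amplitude", c(0.5, 1),
                          seed = 2, duration = 800)
  expect_equal(nrow(sw), 4)
  # each cell equals a stand-alone simulation with the same seed
  m35 <- ca1_model("fig1_2", g_nap = 0.35)
  tr <- simulate_ca1(m35, stim_step(1), duration = 800, seed = 2)
  ev <- classify_events(detect_spikes(tr))
  row <- sw[sw$g_value == 0.35 & sw$axis_value == 1, ]
  expect_equal(row$rate_all, burstres:::event_rates(ev)$rate_all)
  expect_true(all(is.na(sw$error)))
  # frequency axis drives with a sinusoid
  sw2 <- conductance_sweep(m, "g_nap", 0.35, "frequency", 40, seed = 2,
                           duration = 800)
  expect_equal(nrow(sw2), 1)
})

test_that("phase locking of classified events distinguishes bands", {
  # synthetic event series locked to the theta peak of the combined drive
  stim <- stim_theta_gamma()
  ev <- structure(tibble::tibble(time = 25 + 100 * (1:30), type = "BS",
                                 n_spikes = 2L,
                                 preceding_interval = rep(100, 30)),
                  class = c("event_series", class(tibble::tibble())))
  pl <- phase_locking(ev, stim, duration = 3500)
  th_bs <- pl[pl$band == "theta" & pl$type == "BS", ]
  expect_gt(th_bs$plv, 0.99)
  expect_gt(th_bs$pls, 0.99)
  expect_true(is.na(pl$plv[pl$type == "SS"][1]))
})
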