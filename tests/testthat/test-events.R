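test_that("spike detection finds threshold-crossing peaks", {
  tt <- seq(0, 200, 0.5)
  flat <- tibble::tibble(time = tt, v_soma = rep(-70, length(tt)))
  expect_equal(nrow(detect_spikes(flat)), 0)
  # three Gaussian bumps crossing threshold at 50/100/150 ms
  v <- -70 + 80 * (exp(-(tt - 50)^2 / 8) + exp(-(tt - 100)^2 / 8) +
                     exp(-(tt - 150)^2 / 8))
  tr <- structure(tibble::tibble(time = tt, v_soma = v), discard = 0)
  sp <- detect_spikes(tr)
  expect_equal(sp$time, c(50, 100, 150), tolerance = 0.51)
  # two crossings closer than the refractory period count once
  v2 <- -70 + 80 * (exp(-(tt - 50)^2 / 0.02) + exp(-(tt - 50.5)^2 / 0.02))
  tr2 <- structure(tibble::tibble(time = tt, v_soma = v2), discard = 0)
  expect_equal(nrow(detect_spikes(tr2, refractory = 2)), 1)
  # samples inside the transient-discard window are excluded
  tr3 <- structure(tibble::tibble(time = tt, v_soma = v), discard = 80)
  expect_equal(detect_spikes(tr3)$time, c(100, 150), tolerance = 0.51)
})

test_that("burst classification applies the strict 14 ms ISI rule", {
  ev <- classify_events(spike_train(c(0, 10, 100, 300, 305, 312), 0, 400))
  expect_equal(ev$type, c("BS", "SS", "BS"))
  expect_equal(ev$time, c(0, 100, 300))
  expect_equal(ev$n_spikes, c(2L, 1L, 3L))
  expect_equal(ev$preceding_interval, c(NA, 90, 200))
  # the boundary is strict: an ISI of exactly 14 ms does not join a burst
  ev2 <- classify_events(spike_train(c(0, 14), 0, 50))
  expect_equal(ev2$type, c("SS", "SS"))
  ev3 <- classify_events(spike_train(c(0, 13.99), 0, 50))
  expect_equal(ev3$type, "BS")
  # trains with fewer than two spikes are disregarded
  expect_equal(nrow(classify_events(spike_train(5, 0, 50))), 0)
  expect_equal(nrow(classify_events(numeric())), 0)
})

test_that("classification matches a brute-force scan and partitions spikes", {
  set.seed(3)
  for (k in 1:5) {
    times <- sort(cumsum(c(50, sample(c(runif(80, 2, 13), runif(120, 15, 300))))))
    ev <- classify_events(spike_train(times, 0, max(times) + 1))
    # independent brute-force scan over all ISIs
    grp <- 1L
    groups <- integer(length(times))
    groups[1] <- 1L
    for (i in 2:length(times)) {
      if (times[i] - times[i - 1] >= 14) grp <- grp + 1L
      groups[i] <- grp
    }
    sizes <- as.integer(table(groups))
    firsts <- times[!duplicated(groups)]
    expect_equal(ev$time, firsts)
    expect_equal(ev$n_spikes, sizes)
    expect_equal(ev$type, ifelse(sizes >= 2, "BS", "SS"))
    # partition: every spike in exactly one event
    expect_equal(sum(ev$n_spikes), length(times))
    # preceding interval runs from the last spike of the previous event
    lasts <- times[cumsum(sizes)]
    expect_equal(ev$preceding_interval[-1], firsts[-1] - head(lasts, -1))
    # idempotence on the event times of an all-SS train
    ss_only <- ev$time[ev$type == "SS"]
    if (length(ss_only) >= 2) {
      ev2 <- classify_events(spike_train(ss_only, 0, max(times) + 1))
      expect_true(all(ev2$n_spikes[diff(c(-Inf, ev2$time)) >= 14] >= 1))
    }
  }
})

test_that("firing rate is count over window", {
  expect_equal(firing_rate(spike_train(seq(100, 3600, 500), 0, 4000)), 2)
  expect_equal(firing_rate(spike_train(numeric(), 0, 4000)), 0)
  ev <- classify_events(spike_train(sort(runif(20, 0, 2500)), 0, 2500))
  expect_equal(firing_rate(ev), nrow(ev) / 2.5)
})

test_that("CV of the ISI uses the population standard deviation", {
  expect_equal(cv_isi(spike_train(seq(0, 500, 50), 0, 500)), 0)
  isis <- c(5, 5, 200, 5, 5, 200)
  times <- cumsum(c(0, isis))
  m <- mean(isis)
  s <- sqrt(mean((isis - m)^2))
  expect_equal(cv_isi(spike_train(times, 0, 450)), s / m, tolerance = 1e-12)
  expect_true(is.na(cv_isi(spike_train(c(0, 10), 0, 20))))
  expect_true(is.na(is_bursting(spike_train(c(0, 10), 0, 20))))
  expect_true(is_bursting(spike_train(cumsum(c(0, 2, 2, 2, 2, 2, 2, 800)), 0, 900)))
})

test_that("interval-conditioned probabilities are consistent", {
  mk_ev <- function(df) structure(df, class = c("event_series", class(df)))
  all_bs <- mk_ev(tibble::tibble(time = 1:50 * 20, type = "BS",
                                 n_spikes = 2L,
                                 preceding_interval = runif(50, 0, 490)))
  pr <- event_probability_by_interval(all_bs)
  expect_true(all(pr$p_bs[pr$n > 0] == 1))
  # constructed split: BS only above 100 ms, SS only below 60 ms
  ev <- mk_ev(tibble::tibble(
    time = seq_along(c(1:30, 1:30)) * 50,
    type = rep(c("SS", "BS"), each = 30),
    n_spikes = rep(c(1L, 2L), each = 30),
    preceding_interval = c(runif(30, 5, 55), runif(30, 105, 495))))
  pr2 <- event_probability_by_interval(ev)
  expect_true(all(pr2$p_ss[pr2$n > 0 & pr2$bin_hi <= 60] == 1))
  expect_true(all(pr2$p_bs[pr2$n > 0 & pr2$bin_lo >= 100] == 1))
  # occupied bins always satisfy P(BS) + P(SS) = 1
  expect_equal(pr2$p_ss[pr2$n > 0] + pr2$p_bs[pr2$n > 0],
               rep(1, sum(pr2$n > 0)))
  # pooling a list of series adds counts bin by bin
  half1 <- mk_ev(ev[1:30, ]); half2 <- mk_ev(ev[31:60, ])
  pooled <- event_probability_by_interval(list(half1, half2))
  expect_equal(pooled$n, pr2$n)
  expect_error(event_probability_by_interval(mk_ev(ev[0, ])), "no events")
})
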