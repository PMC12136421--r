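#' Synthetic voltage-imaging trace configuration
#'
#' Parameters for generating fluorescence traces that emulate in vivo
#' voltage-imaging recordings of CA1 pyramidal cells (20 s at 600 Hz,
#' negative-polarity spike transients on a single-exponential photobleach
#' trend with Gaussian noise, interleaved single-spike and burst events).
#' Event times follow a renewal process with exponential interevent intervals
#' truncated below `min_interval`; each event is realized as a burst with a
#' probability given by the interval-bias map (bursts are more likely after
#' long quiet intervals, as in the recordings), and an optional
#' theta-modulated mode concentrates events on an 8 Hz cycle.
#'
#' @param duration Trace length, s.
#' @param fs Sampling rate, Hz.
#' @param rate Mean event rate, Hz.
#' @param min_interval Smallest allowed interevent interval, ms.
#' @param interval_breaks,p_bs Interval-bias map: `p_bs[i]` is the burst
#'   probability for preceding intervals in
#'   `[interval_breaks[i], interval_breaks[i+1])`; the last value applies
#'   beyond the last break.
#' @param intraburst_isi Within-burst inter-spike interval, ms (< 14).
#' @param burst_sizes,burst_size_probs Burst spike-count distribution.
#' @param amplitude,rise,decay Transient kernel: peak-normalized difference of
#'   exponentials with these rise/decay constants, ms.
#' @param bleach_b,bleach_tau Photobleach trend `b * exp(-t/tau)` (tau in s).
#' @param baseline Constant fluorescence offset.
#' @param noise_sd Gaussian noise standard deviation.
#' @param polarity `"negative"` flips transients downward.
#' @param theta_mod Amplitude in [0, 1) of 8 Hz sinusoidal modulation of the
#'   event intensity (0 = plain renewal process).
#' @return A list of class `synth_imaging_config`.
#' @export
synth_imaging_config <- function(duration = 20, fs = 600, rate = 3,
                                 min_interval = 20,
                                 interval_breaks = c(0, 150, 300),
                                 p_bs = c(0.1, 0.5, 0.85),
                                 intraburst_isi = 8,
                                 burst_sizes = 2:4,
                                 burst_size_probs = c(0.5, 0.3, 0.2),
                                 amplitude = 1, rise = 2, decay = 10,
                                 bleach_b = 2, bleach_tau = 8,
                                 baseline = 10, noise_sd = 0.02,
                                 polarity = "negative", theta_mod = 0) {
  stopifnot(rate >= 0, intraburst_isi < 14, fs * duration == round(fs * duration),
            length(p_bs) == length(interval_breaks),
            all(p_bs >= 0 & p_bs <= 1), theta_mod >= 0, theta_mod < 1,
            length(burst_sizes) == length(burst_size_probs))
  structure(as.list(environment()), class = "synth_imaging_config")
}

#' Generate a synthetic fluorescence trace with ground truth
#'
#' Realizes the renewal process of [synth_imaging_config()], classifies each
#' event as SS or BS from the interval-bias map, convolves the spikes with the
#' transient kernel, applies polarity, bleach trend and noise, and returns the
#' trace together with the planted ground-truth event series.
#'
#' @param cfg A [synth_imaging_config()].
#' @param seed RNG seed.
#' @param cell Cell identifier for the trace.
#' @return List with `trace` (an [imaging_trace()]) and `truth` (an
#'   `event_series` tibble: `time, type, n_spikes, preceding_interval`).
#' @export
generate_imaging_trace <- function(cfg, seed = 1, cell = "cell1") {
  stopifnot(inherits(cfg, "synth_imaging_config"))
  set.seed(seed)
  dur_ms <- cfg$duration * 1000
  # renewal process: exponential gaps, truncated below min_interval, measured
  # from the previous event's LAST spike (the same convention the interevent
  # interval analysis uses), so planted events never overlap a running burst;
  # optional theta thinning concentrates events on an 8 Hz cycle
  spikes <- numeric()
  truth <- NULL
  prev_spike <- NA_real_
  t <- 0
  repeat {
    gap <- stats::rexp(1, cfg$rate / 1000)
    if (gap < cfg$min_interval) gap <- cfg$min_interval
    t <- t + gap
    if (t >= dur_ms - 100) break
    if (cfg$theta_mod > 0) {
      accept <- stats::runif(1) <
        (1 + cfg$theta_mod * sin(2 * pi * 8 * t / 1000)) / (1 + cfg$theta_mod)
      if (!accept) next
    }
    interval <- if (is.na(prev_spike)) NA_real_ else t - prev_spike
    idx <- findInterval(if (is.na(interval)) 0 else interval,
                        cfg$interval_breaks)
    bs <- stats::runif(1) < cfg$p_bs[max(idx, 1)]
    n_sp <- if (bs)
      sample(cfg$burst_sizes, 1, prob = cfg$burst_size_probs) else 1L
    ev_spikes <- t + (seq_len(n_sp) - 1) * cfg$intraburst_isi
    spikes <- c(spikes, ev_spikes)
    truth <- dplyr::bind_rows(truth, tibble::tibble(
      time = t, type = if (bs) "BS" else "SS", n_spikes = as.integer(n_sp),
      preceding_interval = interval))
    prev_spike <- ev_spikes[n_sp]
    t <- prev_spike
  }
  n <- cfg$duration * cfg$fs
  tt <- (seq_len(n) - 1) / cfg$fs * 1000
  # peak-normalized difference-of-exponentials kernel
  kt <- seq(0, cfg$decay * 8, by = 1000 / cfg$fs)
  kern <- exp(-kt / cfg$decay) - exp(-kt / cfg$rise)
  kern <- kern / max(kern) * cfg$amplitude
  sig <- numeric(n)
  for (sp in spikes) {
    i0 <- floor(sp / 1000 * cfg$fs) + 1
    idx <- i0:min(n, i0 + length(kern) - 1)
    sig[idx] <- sig[idx] + kern[seq_along(idx)]
  }
  if (cfg$polarity == "negative") sig <- -sig
  f <- cfg$baseline + cfg$bleach_b * exp(-tt / 1000 / cfg$bleach_tau) + sig +
    stats::rnorm(n, 0, cfg$noise_sd)
  truth <- structure(truth, window_start = 0, window_end = dur_ms,
                     class = c("event_series", class(tibble::tibble())))
  list(trace = imaging_trace(f, fs = cfg$fs, polarity = cfg$polarity,
                             cell = cell),
       truth = truth)
}

#' Generate a cohort of synthetic cells
#'
#' @param n_cells Number of cells.
#' @param cfg Shared [synth_imaging_config()].
#' @param seed Base seed; cell k uses `seed + k - 1`.
#' @return List of `list(trace, truth)` per cell.
#' @export
generate_imaging_cells <- function(n_cells = 7, cfg = synth_imaging_config(),
                                   seed = 1) {
  purrr::map(seq_len(n_cells), function(k)
    generate_imaging_trace(cfg, seed = seed + k - 1,
                           cell = paste0("cell", k)))
}
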