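#' Spike phases relative to an oscillatory reference
#'
#' Band-passes the reference signal to the requested band (zero-phase
#' forward-backward Butterworth filter), takes the analytic-signal phase
#' (Hilbert transform), and evaluates it at each spike time by interpolating
#' the unwrapped phase. Theta is 3--12 Hz and gamma 30--100 Hz.
#'
#' @param spike_times Spike or event times, ms.
#' @param ref Reference signal samples (typically the stimulus waveform).
#' @param fs Sampling rate of `ref`, Hz.
#' @param band Length-2 numeric band in Hz, or `"theta"` / `"gamma"`.
#' @param order Butterworth order.
#' @return Phases in (-pi, pi], one per spike; empty input gives empty output.
#' @export
spike_phases <- function(spike_times, ref, fs, band = "theta", order = 3) {
  if (is.character(band))
    band <- switch(match.arg(band, c("theta", "gamma")),
                   theta = c(3, 12), gamma = c(30, 100))
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1],
            band[2] < fs / 2)
  if (length(spike_times) == 0) return(numeric())
  filt <- signal::butter(order, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(filt, ref - mean(ref))
  ph <- unwrap_phase(Arg(analytic_signal(x)))
  tt <- (seq_along(ref) - 1) / fs * 1000 # ms
  stopifnot(all(spike_times >= tt[1]), all(spike_times <= tt[length(tt)]))
  out <- approx(tt, ph, xout = spike_times)$y
  wrap_phase(out)
}

# analytic signal x + i H(x) via the FFT construction (positive frequencies
# doubled, negative zeroed)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

wrap_phase <- function(p) {
  out <- (p + pi) %% (2 * pi) - pi
  ifelse(out == -pi, pi, out)
}

#' Phase-locking value
#'
#' Modulus of the mean unit phasor of the spike phases,
#' \eqn{PLV = |N^{-1} \sum_n e^{i\phi_n}|}, in \[0, 1\].
#'
#' @param phases Spike phases, rad (N >= 1).
#' @return PLV; `NA` for an empty phase set.
#' @export
plv <- function(phases) {
  if (length(phases) == 0) return(NA_real_)
  Mod(mean(exp(1i * phases)))
}

#' Phase-locking statistics
#'
#' Sample-size-corrected phase-locking statistic
#' \eqn{PLS = (PLV^2 N - 1)/(N - 1)}, which discounts the positive bias of the
#' PLV at small spike counts so locking of bursts and single spikes can be
#' compared despite unequal numbers. Requires N >= 2; PLS <= 1 always, and
#' PLS = 1 exactly when PLV = 1.
#'
#' @param plv_value PLV in \[0, 1\].
#' @param n Number of spikes behind the PLV.
#' @return PLS; `NA` when `n < 2`.
#' @export
pls <- function(plv_value, n) {
  if (is.na(plv_value) || n < 2) return(NA_real_)
  (plv_value^2 * n - 1) / (n - 1)
}

#' Phase-locking of classified events to a stimulus
#'
#' Computes, per band (theta, gamma) and event type (SS, BS), the PLV and PLS
#' of event times (a burst is represented by its first spike) against the
#' stimulus waveform regenerated at `fs` Hz.
#'
#' @param events An `event_series` from [classify_events()].
#' @param stim The stimulus tibble the trace was driven with.
#' @param duration Trace duration, ms.
#' @param fs Reference sampling rate for phase extraction, Hz.
#' @param bands Named list of bands, Hz.
#' @return A tibble: `band, type, n, plv, pls`.
#' @export
phase_locking <- function(events, stim, duration,
                          fs = 2000,
                          bands = list(theta = c(3, 12), gamma = c(30, 100))) {
  tt <- seq(0, duration, by = 1000 / fs)
  ref <- make_stimulus(stim, tt, "soma") + make_stimulus(stim, tt, "dend")
  grid <- tidyr::expand_grid(band = names(bands), type = c("SS", "BS"))
  purrr::pmap(grid, function(band, type) {
    times <- events$time[events$type == type]
    ph <- spike_phases(times, ref, fs, bands[[band]])
    v <- plv(ph)
    tibble::tibble(band = band, type = type, n = length(ph),
                   plv = v, pls = pls(v, length(ph)))
  }) |> dplyr::bind_rows()
}

#' Two-group comparison: Cohen's d and t-test
#'
#' Cohen's d with pooled (n-1 denominator) standard deviation,
#' \eqn{d = (\bar a - \bar b)/s_{pooled}}, and a two-sided, unpaired,
#' equal-variance t-test. With zero pooled variance, d is 0 when the means are
#' equal and `NA` otherwise.
#'
#' @param a,b Numeric samples (each length >= 2; `NA`s dropped).
#' @return One-row tibble: `cohens_d, t, df, p, n_a, n_b`.
#' @export
compare_groups <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  d <- if (sp2 > 0) (mean(a) - mean(b)) / sqrt(sp2)
       else if (mean(a) == mean(b)) 0 else NA_real_
  tt <- stats::t.test(a, b, var.equal = TRUE)
  tibble::tibble(cohens_d = d, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 n_a = na, n_b = nb)
}
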