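#' Spike trains
#'
#' A spike train is a tibble with a single `time` column (ms, strictly
#' increasing) plus `window_start`/`window_end` attributes giving the analysis
#' window; rates are counts over that window.
#'
#' @param times Spike times, ms, strictly increasing.
#' @param window_start,window_end Analysis window, ms.
#' @return A tibble of class `spike_train`.
#' @export
spike_train <- function(times, window_start, window_end) {
  times <- as.numeric(times)
  stopifnot(window_end > window_start,
            !is.unsorted(times, strictly = TRUE),
            all(times >= window_start), all(times <= window_end))
  structure(tibble::tibble(time = times),
            window_start = window_start, window_end = window_end,
            class = c("spike_train", class(tibble::tibble())))
}

#' Detect spikes in a voltage trace
#'
#' A spike is recorded at every local maximum that follows an upward crossing
#' of `threshold`; the spike time is the time of the local maximum. Crossings
#' within `refractory` ms of the previous spike are ignored, and samples inside
#' the trace's transient-discard window are excluded.
#'
#' @param trace A `ca1_trace` from [simulate_ca1()], or any data frame with
#'   `time` and `v_soma` columns (attributes `discard` optional).
#' @param threshold Detection threshold, mV.
#' @param refractory Minimum inter-spike separation, ms.
#' @return A [spike_train()].
#' @export
detect_spikes <- function(trace, threshold = -10, refractory = 2) {
  discard <- attr(trace, "discard") %||% 0
  keep <- trace$time >= discard
  tt <- trace$time[keep]
  v <- trace$v_soma[keep]
  times <- peak_times(tt, v, threshold, refractory)
  spike_train(times, window_start = discard, window_end = max(trace$time))
}

# threshold-plus-local-max peak picker shared with the imaging pipeline:
# local maxima above threshold; within a refractory period only the larger
# peak survives; with min_rise > 0 a peak must additionally rise by at least
# min_rise above the valley separating it from the previous accepted peak
# (suppresses secondary maxima riding on a slow decay tail while keeping the
# distinct peaks of a burst).
peak_times <- function(tt, v, threshold, refractory, min_rise = 0) {
  n <- length(v)
  if (n < 3) return(numeric())
  above <- v >= threshold
  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n],
              FALSE)
  cand <- which(above & is_max)
  kept <- integer()
  for (i in cand) {
    last <- if (length(kept)) kept[length(kept)] else 0L
    if (last > 0L && tt[i] - tt[last] < refractory) {
      if (v[i] > v[last]) kept[length(kept)] <- i
      next
    }
    valley <- min(v[max(last, 1L):i])
    if (v[i] - valley >= min_rise) kept <- c(kept, i)
  }
  tt[kept]
}

#' Classify single spikes and bursts
#'
#' Maximal runs of consecutive spikes whose inter-spike intervals are strictly
#' below `isi_burst` (default 14 ms) form one burst (BS) event, timed at the
#' run's first spike; isolated spikes are single-spike (SS) events. Trains with
#' fewer than two spikes are disregarded (empty result). Each event carries the
#' quiet interval preceding it: the time from the previous spike of any event
#' (the last spike of a burst counts) to this event's first spike; it is `NA`
#' for the first event.
#'
#' @param train A [spike_train()] or numeric vector of spike times (ms).
#' @param isi_burst Burst-membership ISI window, ms (strict `<`).
#' @return A tibble of class `event_series` with columns
#'   `time, type ("SS"/"BS"), n_spikes, preceding_interval`, and the train's
#'   window attributes.
#' @export
classify_events <- function(train, isi_burst = 14) {
  times <- if (is.data.frame(train)) train$time else as.numeric(train)
  ws <- attr(train, "window_start") %||% if (length(times)) min(times) else 0
  we <- attr(train, "window_end") %||% if (length(times)) max(times) else 1
  empty <- tibble::tibble(time = numeric(), type = character(),
                          n_spikes = integer(),
                          preceding_interval = numeric())
  if (length(times) < 2)
    return(structure(empty, window_start = ws, window_end = we,
                     class = c("event_series", class(empty))))
  isi <- diff(times)
  # event id grows whenever the gap from the previous spike is >= isi_burst
  ev_id <- cumsum(c(1, as.integer(isi >= isi_burst)))
  first <- !duplicated(ev_id)
  n_spikes <- as.integer(table(ev_id))
  ev_time <- times[first]
  prev_spike <- c(NA_real_, times[cumsum(n_spikes)][-length(n_spikes)])
  out <- tibble::tibble(
    time = ev_time,
    type = ifelse(n_spikes >= 2, "BS", "SS"),
    n_spikes = n_spikes,
    preceding_interval = ev_time - prev_spike
  )
  structure(out, window_start = ws, window_end = we,
            class = c("event_series", class(empty)))
}

#' Firing rate
#'
#' Spike (or event) count divided by the analysis window length in seconds.
#'
#' @param x A [spike_train()] or `event_series`.
#' @param window Window length, ms; defaults to the object's window attributes.
#' @return Rate, Hz.
#' @export
firing_rate <- function(x, window = NULL) {
  if (is.null(window))
    window <- (attr(x, "window_end") %||% max(x$time, 1)) -
      (attr(x, "window_start") %||% 0)
  nrow(x) / (window / 1000)
}

# per-type event rates (a burst counts as one event)
event_rates <- function(events, window = NULL) {
  if (is.null(window))
    window <- attr(events, "window_end") - attr(events, "window_start")
  w <- window / 1000
  tibble::tibble(
    rate_ss = sum(events$type == "SS") / w,
    rate_bs = sum(events$type == "BS") / w,
    rate_all = nrow(events) / w
  )
}

#' Coefficient of variation of inter-spike intervals
#'
#' `CV = std(ISI)/mean(ISI)` over successive inter-spike intervals, using the
#' population (n-denominator) standard deviation. At least two ISIs (three
#' spikes) are required; otherwise the value is undefined (`NA`). The
#' burstiness criterion of the analysis is `CV > 2` (see [is_bursting()]).
#'
#' @param train A [spike_train()] or numeric spike times, ms.
#' @return CV (dimensionless) or `NA_real_`.
#' @export
cv_isi <- function(train) {
  times <- if (is.data.frame(train)) train$time else as.numeric(train)
  if (length(times) < 3) return(NA_real_)
  isi <- diff(times)
  m <- mean(isi)
  s <- sqrt(mean((isi - m)^2))
  s / m
}

#' @rdname cv_isi
#' @param threshold Burstiness criterion on CV.
#' @return `is_bursting()`: `TRUE`/`FALSE`/`NA`.
#' @export
is_bursting <- function(train, threshold = 2) {
  cv <- cv_isi(train)
  if (is.na(cv)) NA else cv > threshold
}

#' Event probability conditioned on the preceding quiet interval
#'
#' Pools events (from one run or a list of runs), bins them by the quiet
#' interval preceding each event, and computes per bin the conditional
#' probability that an event is a burst or a single spike, together with each
#' type's normalized interval density (per-type histogram normalized over that
#' type's own events, per ms).
#'
#' @param events An `event_series` or a list of them (pooled).
#' @param breaks Bin edges, ms (default 10-ms bins over 0--500 ms).
#' @return A tibble with columns `bin_lo, bin_hi, n_ss, n_bs, n, p_ss, p_bs,
#'   dens_ss, dens_bs`; `p_*` are `NA` in empty bins and satisfy
#'   `p_ss + p_bs = 1` in occupied bins.
#' @export
event_probability_by_interval <- function(events, breaks = seq(0, 500, 10)) {
  if (!is.data.frame(events)) events <- dplyr::bind_rows(events)
  ev <- events[!is.na(events$preceding_interval), , drop = FALSE]
  if (nrow(ev) == 0) stop("no events with a defined preceding interval",
                          call. = FALSE)
  bin <- cut(ev$preceding_interval, breaks, right = FALSE)
  width <- diff(breaks)
  n_ss_tot <- sum(ev$type == "SS")
  n_bs_tot <- sum(ev$type == "BS")
  tab <- table(bin, factor(ev$type, levels = c("SS", "BS")))
  n_ss <- as.integer(tab[, "SS"])
  n_bs <- as.integer(tab[, "BS"])
  n <- n_ss + n_bs
  tibble::tibble(
    bin_lo = breaks[-length(breaks)],
    bin_hi = breaks[-1],
    n_ss = n_ss, n_bs = n_bs, n = n,
    p_ss = ifelse(n > 0, n_ss / n, NA_real_),
    p_bs = ifelse(n > 0, n_bs / n, NA_real_),
    dens_ss = if (n_ss_tot > 0) n_ss / n_ss_tot / width else NA_real_,
    dens_bs = if (n_bs_tot > 0) n_bs / n_bs_tot / width else NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
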