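#' Firing-rate tuning curve over input frequency
#'
#' Sweeps a sinusoidal drive over a frequency grid and records, per frequency,
#' the single-spike (SS), burst (BS) and total event rates and the ISI
#' coefficient of variation. A burst counts as one event. With `n_runs > 1` the
#' reported rates are ensemble means (seeds `seed, seed + 1, ...` per run) and
#' per-frequency standard deviations are included.
#'
#' @param model A [ca1_model()].
#' @param freqs Frequency grid, Hz, strictly increasing, minimum 2 Hz.
#' @param amplitude Sinusoid amplitude, uA/cm^2.
#' @param offset Constant holding current added to the sinusoid, uA/cm^2.
#' @param n_runs Runs per frequency.
#' @param seed Base RNG seed.
#' @param duration,dt,discard Passed to [simulate_ca1()].
#' @param isi_burst Burst-classification window, ms.
#' @return A tibble of class `tuning_curve`: `freq, rate_ss, rate_bs, rate_all,
#'   cv` (+ `sd_*` columns when `n_runs > 1`).
#' @export
tuning_curve <- function(model, freqs = seq(2, 100, 2), amplitude = 1,
                         offset = 0, n_runs = 1, seed = 1,
                         duration = 4000, dt = 0.02, discard = 100,
                         isi_burst = 14) {
  stopifnot(!is.unsorted(freqs, strictly = TRUE), min(freqs) >= 2)
  one <- function(f) {
    stim <- stim_sine(f, amplitude)
    if (offset != 0) stim <- stim_combine(stim, stim_step(offset))
    runs <- purrr::map(seq_len(n_runs) - 1L, function(k) {
      tr <- simulate_ca1(model, stim, duration = duration, dt = dt,
                         discard = discard, seed = seed + k)
      sp <- detect_spikes(tr)
      ev <- classify_events(sp, isi_burst)
      dplyr::bind_cols(event_rates(ev), tibble::tibble(cv = cv_isi(sp)))
    })
    runs <- dplyr::bind_rows(runs)
    out <- dplyr::summarise(runs, dplyr::across(dplyr::everything(),
                                                ~mean(.x, na.rm = TRUE)))
    if (n_runs > 1) {
      sds <- dplyr::summarise(runs, dplyr::across(dplyr::everything(),
                                                  ~sd(.x, na.rm = TRUE)))
      names(sds) <- paste0("sd_", names(sds))
      out <- dplyr::bind_cols(out, sds)
    }
    dplyr::bind_cols(tibble::tibble(freq = f), out)
  }
  out <- dplyr::bind_rows(purrr::map(freqs, one))
  out$cv[is.nan(out$cv)] <- NA_real_
  class(out) <- c("tuning_curve", class(out))
  out
}

#' Resonance summary of interleaved SS and BS tuning curves
#'
#' Finds each event type's resonance frequency (argmax of its rate over the
#' swept grid; ties broken toward the lower frequency) and amplitude (the rate
#' at that frequency), and the interleaving differences
#' \eqn{\Delta f = f_{SS} - f_{BS}} and \eqn{\Delta A = A_{SS} - A_{BS}}.
#' An all-zero curve yields `NA` for that type (no resonance to summarize).
#'
#' @param curve A `tuning_curve` (columns `freq, rate_ss, rate_bs`).
#' @return A one-row tibble of class `resonance_summary`:
#'   `f_ss, f_bs, a_ss, a_bs, delta_f, delta_a`.
#' @export
resonance_summary <- function(curve) {
  argmax <- function(rate) {
    if (all(rate == 0) || all(is.na(rate))) return(NA_integer_)
    which.max(rate) # first index on ties -> lowest frequency
  }
  i_ss <- argmax(curve$rate_ss)
  i_bs <- argmax(curve$rate_bs)
  out <- tibble::tibble(
    f_ss = if (is.na(i_ss)) NA_real_ else curve$freq[i_ss],
    f_bs = if (is.na(i_bs)) NA_real_ else curve$freq[i_bs],
    a_ss = if (is.na(i_ss)) NA_real_ else curve$rate_ss[i_ss],
    a_bs = if (is.na(i_bs)) NA_real_ else curve$rate_bs[i_bs]
  )
  out$delta_f <- out$f_ss - out$f_bs
  out$delta_a <- out$a_ss - out$a_bs
  class(out) <- c("resonance_summary", class(out))
  out
}

#' Sweep one conductance against input amplitude or frequency
#'
#' Long-format heatmap table: for each grid cell (conductance value x axis
#' value) the model is simulated and spike statistics recorded. With
#' `axis = "amplitude"` the input is a step current of that amplitude; with
#' `axis = "frequency"` a sinusoid of `amplitude` at that frequency.
#' Failures in single cells are recorded in the `error` column and the sweep
#' continues.
#'
#' @param model Base [ca1_model()].
#' @param conductance Parameter name to vary (e.g. `"g_nap"`).
#' @param values Conductance grid, mS/cm^2.
#' @param axis `"amplitude"` or `"frequency"`.
#' @param axis_values Grid for the second axis (uA/cm^2 or Hz).
#' @param amplitude Sinusoid amplitude when `axis = "frequency"`.
#' @param seed,duration,dt,discard,isi_burst As in [tuning_curve()].
#' @return A tibble with columns `g_value, axis_value, rate_ss, rate_bs,
#'   rate_all, cv, error`.
#' @export
conductance_sweep <- function(model, conductance, values,
                              axis = c("amplitude", "frequency"),
                              axis_values, amplitude = 1, seed = 1,
                              duration = 4000, dt = 0.02, discard = 100,
                              isi_burst = 14) {
  axis <- match.arg(axis)
  stopifnot(conductance %in% names(model$par))
  grid <- tidyr::expand_grid(g_value = values, axis_value = axis_values)
  one <- function(g_value, axis_value) {
    res <- tibble::tibble(g_value = g_value, axis_value = axis_value,
                          rate_ss = NA_real_, rate_bs = NA_real_,
                          rate_all = NA_real_, cv = NA_real_,
                          error = NA_character_)
    m <- model
    m$par[[conductance]] <- g_value
    stim <- if (axis == "amplitude") stim_step(axis_value)
            else stim_sine(axis_value, amplitude)
    tr <- try(simulate_ca1(m, stim, duration = duration, dt = dt,
                           discard = discard, seed = seed), silent = TRUE)
    if (inherits(tr, "try-error")) {
      res$error <- conditionMessage(attr(tr, "condition"))
      return(res)
    }
    sp <- detect_spikes(tr)
    ev <- classify_events(sp, isi_burst)
    r <- event_rates(ev)
    res$rate_ss <- r$rate_ss; res$rate_bs <- r$rate_bs
    res$rate_all <- r$rate_all; res$cv <- cv_isi(sp)
    res
  }
  purrr::pmap(grid, one) |> dplyr::bind_rows()
}
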