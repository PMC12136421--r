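#' Stimulus components
#'
#' A stimulus is a tibble of additive components, each a step or a sinusoid,
#' targeted at the soma or the dendrite. A step contributes `amplitude` for
#' `t >= onset`; a sinusoid contributes
#' `amplitude * sin(2*pi*frequency*(t-onset)/1000 + phase)` for `t >= onset`
#' and 0 before. Combine components with [stim_combine()] (or `rbind`).
#'
#' @param amplitude Current density, uA/cm^2.
#' @param frequency Sinusoid frequency, Hz (> 0).
#' @param phase Initial phase at onset, rad.
#' @param onset Start time, ms (>= 0).
#' @param target `"soma"` or `"dend"`.
#' @return A tibble of class `ca1_stimulus` with columns
#'   `kind, amplitude, frequency, phase, onset, target`.
#' @examples
#' stim_theta_gamma() # 10 Hz amp 1 + 40 Hz amp 2, the combined drive
#' @name stimulus
NULL

new_stimulus <- function(kind, amplitude, frequency, phase, onset, target) {
  stopifnot(onset >= 0, target %in% c("soma", "dend"))
  out <- tibble::tibble(kind = kind, amplitude = amplitude,
                        frequency = frequency, phase = phase,
                        onset = onset, target = target)
  class(out) <- c("ca1_stimulus", class(out))
  out
}

#' @rdname stimulus
#' @export
stim_step <- function(amplitude = 1, onset = 0, target = "soma") {
  new_stimulus("step", amplitude, NA_real_, NA_real_, onset, target)
}

#' @rdname stimulus
#' @export
stim_sine <- function(frequency, amplitude = 1, phase = 0, onset = 0,
                      target = "soma") {
  stopifnot(frequency > 0)
  new_stimulus("sinusoid", amplitude, frequency, phase, onset, target)
}

#' @rdname stimulus
#' @param ... Stimuli to combine.
#' @export
stim_combine <- function(...) {
  out <- dplyr::bind_rows(...)
  class(out) <- unique(c("ca1_stimulus", class(out)))
  out
}

#' @rdname stimulus
#' @param f_theta,a_theta Theta component frequency (Hz) and amplitude.
#' @param f_gamma,a_gamma Gamma component frequency (Hz) and amplitude.
#' @export
stim_theta_gamma <- function(f_theta = 10, a_theta = 1,
                             f_gamma = 40, a_gamma = 2, target = "soma") {
  stim_combine(stim_sine(f_theta, a_theta, target = target),
               stim_sine(f_gamma, a_gamma, target = target))
}

#' Evaluate a stimulus on a time base
#'
#' @param stim A `ca1_stimulus` tibble (or `NULL` for no input).
#' @param time Time base, ms.
#' @param target Which compartment's waveform to build.
#' @return Numeric current series, uA/cm^2.
#' @export
make_stimulus <- function(stim, time, target = "soma") {
  out <- numeric(length(time))
  if (is.null(stim) || nrow(stim) == 0) return(out)
  comp <- stim[stim$target == target, , drop = FALSE]
  for (i in seq_len(nrow(comp))) {
    on <- time >= comp$onset[i]
    if (comp$kind[i] == "step") {
      out[on] <- out[on] + comp$amplitude[i]
    } else {
      out[on] <- out[on] + comp$amplitude[i] *
        sin(2 * pi * comp$frequency[i] * (time[on] - comp$onset[i]) / 1000 +
              comp$phase[i])
    }
  }
  out
}
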