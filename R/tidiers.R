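#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a resonance summary
#'
#' @param x A `resonance_summary`.
#' @param ... Unused.
#' @return A long tibble with one row per quantity (`f_ss`, `f_bs`, `a_ss`,
#'   `a_bs`, `delta_f`, `delta_a`).
#' @export
tidy.resonance_summary <- function(x, ...) {
  tibble::tibble(quantity = names(x)[1:6],
                 value = as.numeric(x[1, 1:6]))
}

#' Tidy per-area imaging statistics
#'
#' @param x An `area_stats` object.
#' @param ... Unused.
#' @return The per-area summary tibble (means, Cohen's d, t, p).
#' @export
tidy.area_stats <- function(x, ...) x$summary

#' One-row summary of per-area imaging statistics
#'
#' @param x An `area_stats` object.
#' @param ... Unused.
#' @return A one-row tibble: number of cells and areas, d direction, smallest
#'   p value.
#' @export
glance.area_stats <- function(x, ...) {
  tibble::tibble(n_cells = length(unique(x$per_cell$cell)),
                 n_areas = nrow(x$areas),
                 direction = x$direction,
                 paired = x$paired,
                 min_p = suppressWarnings(min(x$summary$p, na.rm = TRUE)))
}

#' Tidy a simulated trace
#'
#' @param x A `ca1_trace`.
#' @param ... Unused.
#' @return The trace as a plain tibble in long format (`time`, `series`,
#'   `value`).
#' @export
tidy.ca1_trace <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"time",
                      names_to = "series", values_to = "value")
}

#' One-row summary of a simulated trace
#'
#' @param x A `ca1_trace`.
#' @param threshold,refractory Spike-detection settings.
#' @param ... Unused.
#' @return A one-row tibble: duration, dt, spike count, firing rate, CV, and
#'   SS/BS event counts.
#' @export
glance.ca1_trace <- function(x, threshold = -10, refractory = 2, ...) {
  sp <- detect_spikes(x, threshold, refractory)
  ev <- classify_events(sp)
  tibble::tibble(duration = attr(x, "duration"), dt = attr(x, "dt"),
                 n_spikes = nrow(sp), rate = firing_rate(sp),
                 cv = cv_isi(sp), n_ss = sum(ev$type == "SS"),
                 n_bs = sum(ev$type == "BS"))
}
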