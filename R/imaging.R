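#' Voltage-imaging fluorescence traces
#'
#' A fluorescence trace is a tibble with `time` (ms) and `f` (arbitrary
#' fluorescence units) plus attributes `fs` (Hz), `polarity`
#' (`"negative"` for indicators whose emission falls when the membrane
#' depolarizes, `"positive"` otherwise) and `cell` (identifier).
#'
#' @param f Fluorescence samples.
#' @param fs Sampling rate, Hz.
#' @param polarity `"negative"` or `"positive"`.
#' @param cell Cell identifier.
#' @return A tibble of class `imaging_trace`.
#' @export
imaging_trace <- function(f, fs = 600, polarity = c("negative", "positive"),
                          cell = "cell1") {
  polarity <- match.arg(polarity)
  stopifnot(fs > 0, all(is.finite(f)))
  structure(tibble::tibble(time = (seq_along(f) - 1) / fs * 1000, f = f),
            fs = fs, polarity = polarity, cell = cell,
            class = c("imaging_trace", class(tibble::tibble())))
}

#' Read / write plain-text fluorescence traces
#'
#' One fluorescence value per line, with metadata header lines of the form
#' `# fs_hz=600`, `# polarity=negative`, `# cell=cell1`.
#'
#' @param path File path.
#' @return `read_imaging_trace()`: an [imaging_trace()].
#' @export
read_imaging_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, "\\s*="), hdr, value = TRUE)
    if (length(m) == 0) return(default)
    trimws(sub(".*=", "", m[1]))
  }
  vals <- as.numeric(lines[!grepl("^#", lines) & nzchar(trimws(lines))])
  imaging_trace(vals, fs = as.numeric(get("fs_hz", "600")),
                polarity = get("polarity", "negative"),
                cell = get("cell", "cell1"))
}

#' @rdname read_imaging_trace
#' @param trace An [imaging_trace()].
#' @export
write_imaging_trace <- function(trace, path) {
  hdr <- c(paste0("# fs_hz=", attr(trace, "fs")),
           paste0("# polarity=", attr(trace, "polarity")),
           paste0("# cell=", attr(trace, "cell")))
  writeLines(c(hdr, format(trace$f, trim = TRUE)), path)
  invisible(path)
}

#' Photobleach correction
#'
#' Fits a single-exponential decay \eqn{a + b e^{-t/\tau}} to the trace's slow
#' trend (a 250 ms running median, which suppresses the sparse spike
#' transients that would otherwise bias the fit) by nonlinear least squares,
#' initialized from a log-linear fit, and subtracts the fitted curve from the
#' raw trace. If the exponential fit does not converge the trace is linearly
#' detrended instead and the fallback is flagged in the output metadata.
#'
#' @param trace An [imaging_trace()].
#' @param tau_bounds Bounds for the decay constant, s.
#' @return The corrected `imaging_trace`; attributes `bleach_fit`
#'   (`a`, `b`, `tau_s`, `method`).
#' @export
correct_photobleach <- function(trace, tau_bounds = NULL) {
  t_s <- trace$time / 1000
  y <- trace$f
  stopifnot(length(y) >= 10)
  if (is.null(tau_bounds)) tau_bounds <- c(0.1, 10 * max(t_s))
  # slow trend: 250 ms running median kills spike transients
  k <- max(3, round(0.25 * attr(trace, "fs"))); if (k %% 2 == 0) k <- k + 1
  trend <- stats::runmed(y, k)
  a0 <- trend[length(trend)]
  b0 <- trend[1] - a0
  resid0 <- trend - a0
  tau0 <- if (abs(b0) > 1e-12 && sum(resid0 / b0 > 0.05) > 2) {
    pos <- which(resid0 / b0 > 0.05)
    fit <- stats::lm(log(resid0[pos] / b0) ~ t_s[pos])
    max(tau_bounds[1], min(tau_bounds[2], -1 / coef(fit)[2]))
  } else max(t_s) / 3
  fit <- try(minpack.lm::nlsLM(
    trend ~ a + b * exp(-t_s / tau),
    start = list(a = a0, b = b0, tau = tau0),
    lower = c(-Inf, -Inf, tau_bounds[1]),
    upper = c(Inf, Inf, tau_bounds[2]),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (!inherits(fit, "try-error")) {
    cf <- coef(fit)
    corrected <- y - (cf[["a"]] + cf[["b"]] * exp(-t_s / cf[["tau"]]))
    info <- list(a = cf[["a"]], b = cf[["b"]], tau_s = cf[["tau"]],
                 method = "exponential")
  } else {
    lf <- stats::lm(y ~ t_s)
    corrected <- unname(stats::residuals(lf))
    info <- list(a = coef(lf)[[1]], b = coef(lf)[[2]], tau_s = NA_real_,
                 method = "linear_fallback")
  }
  out <- trace
  out$f <- corrected
  attr(out, "bleach_fit") <- info
  out
}

#' Detect spike events in a fluorescence trace
#'
#' Negative-polarity traces are inverted; events are local maxima exceeding
#' `median + k_mad * MAD`, with a minimum inter-peak distance of one
#' refractory period and a prominence requirement (each peak must rise by at
#' least `k_mad * MAD` above the valley separating it from the previous one,
#' so secondary maxima on the slow decay tail of an indicator transient are
#' not counted). Event times are the peak samples. Detection is invariant to
#' affine rescaling of the fluorescence values.
#'
#' @param trace A bleach-corrected [imaging_trace()].
#' @param k_mad Threshold in robust standard deviations above the median.
#' @param refractory Minimum inter-event distance, ms.
#' @return A [spike_train()] of event times, ms.
#' @export
detect_events_fluorescence <- function(trace, k_mad = 4, refractory = 5) {
  y <- if (attr(trace, "polarity") == "negative") -trace$f else trace$f
  thr <- median(y) + k_mad * mad(y)
  times <- peak_times(trace$time, y, thr, refractory,
                      min_rise = k_mad * mad(y))
  spike_train(times, window_start = 0, window_end = max(trace$time))
}

#' Per-area interevent-interval statistics across cells
#'
#' For each cell's classified events, builds per-type (SS, BS) probability
#' density functions of the preceding quiet interval (each type normalized
#' over its own events), sums the density mass inside each analysis area, and
#' compares BS against SS masses across cells per area with Cohen's d and a
#' t-test. The default areas follow the low / intermediate / long interval
#' windows (100--150, 150--250, 400--500 ms). The default direction is
#' `d = (BS - SS)/s`, so positive d means burst-dominant mass in that area.
#'
#' @param events_by_cell List of `event_series`, one per cell (>= 2 cells).
#' @param areas Data frame with `lo`, `hi` columns, ms.
#' @param breaks Histogram bin edges for the densities, ms.
#' @param paired Paired (per-cell differences) or pooled two-sample test.
#' @param direction `"bs_minus_ss"` or `"ss_minus_bs"`.
#' @return An object of class `area_stats`: list with `per_cell` (long tibble
#'   of per-cell area masses) and `summary` (per-area tibble with means,
#'   `cohens_d`, `t`, `p`).
#' @export
area_stats <- function(events_by_cell,
                       areas = tibble::tibble(area = c("low", "intermediate",
                                                       "long"),
                                              lo = c(100, 150, 400),
                                              hi = c(150, 250, 500)),
                       breaks = seq(0, 500, 10), paired = TRUE,
                       direction = c("bs_minus_ss", "ss_minus_bs")) {
  direction <- match.arg(direction)
  stopifnot(length(events_by_cell) >= 2, all(areas$hi > areas$lo))
  per_cell <- purrr::imap(events_by_cell, function(ev, i) {
    dens <- event_probability_by_interval(ev, breaks)
    purrr::pmap(areas, function(area, lo, hi) {
      sel <- dens$bin_lo >= lo & dens$bin_hi <= hi
      w <- dens$bin_hi[sel] - dens$bin_lo[sel]
      tibble::tibble(cell = as.character(i), area = area,
                     mass_ss = sum(dens$dens_ss[sel] * w),
                     mass_bs = sum(dens$dens_bs[sel] * w))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  summ <- per_cell |>
    dplyr::group_by(.data$area) |>
    dplyr::group_modify(function(df, key) {
      bs <- df$mass_bs; ss <- df$mass_ss
      ok <- is.finite(bs) & is.finite(ss)
      bs <- bs[ok]; ss <- ss[ok]
      if (direction == "ss_minus_bs") { tmp <- bs; bs <- ss; ss <- tmp }
      if (length(bs) < 2 || (sd(bs) == 0 && sd(ss) == 0))
        return(tibble::tibble(mean_ss = mean(ss), mean_bs = mean(bs),
                              cohens_d = NA_real_, t = NA_real_,
                              p = NA_real_, n_cells = length(bs)))
      if (paired) {
        dd <- bs - ss
        if (sd(dd) > 0) {
          tt <- stats::t.test(dd)
          d <- mean(dd) / sd(dd)
          tstat <- unname(tt$statistic); pval <- tt$p.value
        } else { # constant difference: direction well-defined, test is not
          d <- if (mean(dd) == 0) 0 else sign(mean(dd)) * Inf
          tstat <- NA_real_; pval <- NA_real_
        }
        tibble::tibble(mean_ss = mean(ss), mean_bs = mean(bs), cohens_d = d,
                       t = tstat, p = pval,
                       n_cells = length(dd))
      } else {
        cg <- compare_groups(bs, ss)
        tibble::tibble(mean_ss = mean(ss), mean_bs = mean(bs),
                       cohens_d = cg$cohens_d, t = cg$t, p = cg$p,
                       n_cells = length(bs))
      }
    }) |>
    dplyr::ungroup()
  if (direction == "ss_minus_bs")
    names(summ)[names(summ) == "mean_ss"] <- "mean_ss" # unchanged layout
  structure(list(per_cell = per_cell, summary = summ,
                 areas = areas, direction = direction, paired = paired),
            class = "area_stats")
}

#' @export
print.area_stats <- function(x, ...) {
  cat("<area_stats>", nrow(x$areas), "areas,",
      length(unique(x$per_cell$cell)), "cells; d direction:",
      x$direction, if (x$paired) "(paired)\n" else "(pooled)\n")
  print(x$summary)
  invisible(x)
}
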