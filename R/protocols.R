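#' Conductance conditions of the two-compartment analyses
#'
#' The low/medium/high triples explored for the persistent-sodium,
#' delayed-rectifier and h-current conductances; each condition varies one
#' conductance with the others at the `fig3_7` defaults.
#'
#' @return A tibble with columns `conductance, level, value`.
#' @export
fig3_conditions <- function() {
  tibble::tibble(
    conductance = rep(c("g_nap", "g_kdr", "g_h"), each = 3),
    level = rep(c("low", "medium", "high"), 3),
    value = c(0, 0.5, 1.5, 0, 5, 10, 0, 2, 5)
  )
}

#' Phase-locking experiment over an ensemble
#'
#' Runs `n_runs` simulations (seeds `seed, seed + 1, ...`), classifies events,
#' and computes PLV / PLS per band and event type for every run; the drive
#' defaults to the combined theta (10 Hz, amplitude 1) + gamma (40 Hz,
#' amplitude 2) input.
#'
#' @param model A [ca1_model()].
#' @param stim Stimulus tibble.
#' @param n_runs Number of simulations.
#' @param seed Base seed.
#' @param duration,dt,discard Passed to [simulate_ca1()].
#' @param isi_burst Burst window, ms.
#' @return A tibble: `run, band, type, n, plv, pls`.
#' @export
pls_experiment <- function(model, stim = stim_theta_gamma(), n_runs = 10,
                           seed = 1, duration = 4000, dt = 0.02,
                           discard = 100, isi_burst = 14) {
  purrr::map(seq_len(n_runs), function(k) {
    tr <- simulate_ca1(model, stim, duration = duration, dt = dt,
                       discard = discard, seed = seed + k - 1)
    ev <- classify_events(detect_spikes(tr), isi_burst)
    dplyr::bind_cols(tibble::tibble(run = k),
                     phase_locking(ev, stim, duration))
  }) |> dplyr::bind_rows()
}

#' Effect size of burst vs single-spike phase locking
#'
#' From a [pls_experiment()] table, compares the per-run PLS of bursts against
#' single spikes in one band: Cohen's d (pooled s.d., BS minus SS) and the
#' unpaired two-sided t-test. Runs whose PLS is undefined (fewer than two
#' events of a type) are dropped from that type's sample.
#'
#' @param pls_table Output of [pls_experiment()].
#' @param band Band name present in the table.
#' @return One-row tibble: `band, cohens_d, t, df, p, n_bs, n_ss` (runs used).
#' @export
pls_effect <- function(pls_table, band = "theta") {
  tb <- pls_table[pls_table$band == band, ]
  bs <- tb$pls[tb$type == "BS"]; bs <- bs[!is.na(bs)]
  ss <- tb$pls[tb$type == "SS"]; ss <- ss[!is.na(ss)]
  if (length(bs) < 2 || length(ss) < 2)
    return(tibble::tibble(band = band, cohens_d = NA_real_, t = NA_real_,
                          df = NA_real_, p = NA_real_,
                          n_bs = length(bs), n_ss = length(ss)))
  cg <- compare_groups(bs, ss)
  tibble::tibble(band = band, cohens_d = cg$cohens_d, t = cg$t, df = cg$df,
                 p = cg$p, n_bs = length(bs), n_ss = length(ss))
}

#' Quiet-interval experiment over an ensemble
#'
#' Pools classified events over `n_runs` simulations and bins the burst /
#' single-spike probabilities by the preceding quiet interval.
#'
#' @inheritParams pls_experiment
#' @param breaks Interval bin edges, ms.
#' @return List with `events` (pooled tibble) and `probability` (per-bin
#'   tibble from [event_probability_by_interval()]).
#' @export
interval_experiment <- function(model, stim = stim_theta_gamma(), n_runs = 10,
                                seed = 1, breaks = seq(0, 500, 10),
                                duration = 4000, dt = 0.02, discard = 100,
                                isi_burst = 14) {
  events <- purrr::map(seq_len(n_runs), function(k) {
    tr <- simulate_ca1(model, stim, duration = duration, dt = dt,
                       discard = discard, seed = seed + k - 1)
    ev <- classify_events(detect_spikes(tr), isi_burst)
    if (nrow(ev)) dplyr::bind_cols(tibble::tibble(run = k), ev) else NULL
  }) |> dplyr::bind_rows()
  prob <- if (nrow(events) && any(!is.na(events$preceding_interval)))
    event_probability_by_interval(events, breaks) else NULL
  list(events = events, probability = prob)
}

#' Run a full figure-style protocol
#'
#' Config-driven entry points reproducing the study protocols end to end.
#' Protocols: `fig1_step_sweep` (step-current conductance/amplitude heatmaps),
#' `fig2_freq_sweep` (single-sinusoid frequency/conductance heatmaps, soma-only
#' profile), `fig3_interleaved` (SS/BS tuning curves and resonance summaries,
#' two-compartment profile), `fig4_pls` (theta/gamma phase-locking statistics
#' with effect sizes over 10 simulations per condition), `fig5_heatmaps`
#' (per-type rate heatmaps over each conductance), `fig6_intervals`
#' (quiet-interval probabilities, combined input), `fig7_single_band` (same,
#' gamma-only and theta-only), `fig8_imaging` (synthetic voltage-imaging
#' cohort through the fluorescence pipeline).
#'
#' All randomness derives from `seed` (condition and run indices offset it).
#' With `reduced = TRUE` the grids and run counts are shrunk for quick runs.
#'
#' @param protocol Protocol id (see Details).
#' @param reduced Use reduced grids / run counts.
#' @param seed Base seed.
#' @param n_runs Runs per condition (default depends on the protocol).
#' @param out_dir If non-`NULL`, tables are written there as CSV and the
#'   summary as JSON (requires the jsonlite package).
#' @param overrides Named list of model-parameter overrides applied on top of
#'   the protocol's profile.
#' @return A list with the protocol's tables and a `config` element recording
#'   the fully resolved settings.
#' @export
run_protocol <- function(protocol = c("fig1_step_sweep", "fig2_freq_sweep",
                                      "fig3_interleaved", "fig4_pls",
                                      "fig5_heatmaps", "fig6_intervals",
                                      "fig7_single_band", "fig8_imaging"),
                         reduced = FALSE, seed = 1, n_runs = NULL,
                         out_dir = NULL, overrides = list()) {
  protocol <- match.arg(protocol)
  mk <- function(profile, ...)
    do.call(ca1_model, c(list(profile), list(...), overrides))
  cfg <- list(protocol = protocol, reduced = reduced, seed = seed,
              overrides = overrides)
  out <- switch(protocol,
    fig1_step_sweep = {
      gn <- if (reduced) c(0.1, 0.35) else seq(0.05, 1, 0.05)
      gk <- if (reduced) c(4, 8) else seq(1, 10, 0.5)
      amps <- if (reduced) 1 else seq(0.25, 2, 0.25)
      list(
        g_nap = conductance_sweep(mk("fig1_2"), "g_nap", gn, "amplitude",
                                  amps, seed = seed),
        g_kdr = conductance_sweep(mk("fig1_2"), "g_kdr", gk, "amplitude",
                                  amps, seed = seed)
      )
    },
    fig2_freq_sweep = {
      gn <- if (reduced) c(0.1, 0.35) else seq(0.05, 1, 0.05)
      gk <- if (reduced) c(4, 8) else seq(1, 10, 0.5)
      fr <- if (reduced) c(8, 40) else seq(2, 100, 2)
      list(
        g_nap = conductance_sweep(mk("fig1_2"), "g_nap", gn, "frequency",
                                  fr, seed = seed),
        g_kdr = conductance_sweep(mk("fig1_2"), "g_kdr", gk, "frequency",
                                  fr, seed = seed)
      )
    },
    fig3_interleaved = {
      nr <- n_runs %||% if (reduced) 1 else 3
      fr <- if (reduced) seq(4, 60, 8) else seq(2, 100, 2)
      conds <- fig3_conditions()
      if (reduced) conds <- conds[conds$level != "low", ]
      res <- purrr::pmap(conds, function(conductance, level, value) {
        m <- mk("fig3_7")
        m$par[[conductance]] <- value
        cv <- tuning_curve(m, fr, amplitude = 1, n_runs = nr, seed = seed)
        summ <- resonance_summary(cv)
        list(curve = dplyr::bind_cols(
               tibble::tibble(conductance = conductance, level = level,
                              value = value), cv),
             summary = dplyr::bind_cols(
               tibble::tibble(conductance = conductance, level = level,
                              value = value), summ))
      })
      list(curves = dplyr::bind_rows(purrr::map(res, "curve")),
           summaries = dplyr::bind_rows(purrr::map(res, "summary")))
    },
    fig4_pls = {
      nr <- n_runs %||% if (reduced) 3 else 10
      conds <- fig3_conditions()
      if (reduced) conds <- conds[conds$level == "medium", ]
      res <- purrr::pmap(conds, function(conductance, level, value) {
        m <- mk("fig3_7")
        m$par[[conductance]] <- value
        tb <- pls_experiment(m, n_runs = nr,
                             seed = seed + 1000 * which(
                               paste(conds$conductance, conds$level) ==
                                 paste(conductance, level)))
        eff <- dplyr::bind_rows(pls_effect(tb, "theta"),
                                pls_effect(tb, "gamma"))
        key <- tibble::tibble(conductance = conductance, level = level,
                              value = value)
        list(pls = dplyr::bind_cols(key[rep(1, nrow(tb)), ], tb),
             effects = dplyr::bind_cols(key[rep(1, nrow(eff)), ], eff))
      })
      list(pls = dplyr::bind_rows(purrr::map(res, "pls")),
           effects = dplyr::bind_rows(purrr::map(res, "effects")))
    },
    fig5_heatmaps = {
      fr <- if (reduced) c(8, 40) else seq(2, 100, 2)
      sweeps <- list(g_ka = c(0, 1.4, 2.8), g_fkca = c(0, 4.5, 9.05),
                     g_kdr = c(0, 5, 10), g_km = c(0, 1.2, 2.4),
                     g_nap = c(0, 0.5, 1.5), g_skca = c(0, 1.4, 2.8))
      if (reduced) sweeps <- sweeps[c("g_kdr", "g_nap")]
      purrr::imap(sweeps, function(vals, g)
        conductance_sweep(mk("fig3_7"), g, vals, "frequency", fr,
                          seed = seed))
    },
    fig6_intervals = interval_protocol(mk, stim_theta_gamma(), reduced,
                                       seed, n_runs),
    fig7_single_band = list(
      gamma_only = interval_protocol(mk, stim_sine(40, 2), reduced, seed,
                                     n_runs),
      theta_only = interval_protocol(mk, stim_sine(10, 1), reduced,
                                     seed + 500, n_runs)
    ),
    fig8_imaging = {
      nc <- if (reduced) 3 else 7
      cells <- generate_imaging_cells(nc, synth_imaging_config(), seed = seed)
      proc <- purrr::map(cells, function(cl) {
        corrected <- correct_photobleach(cl$trace)
        ev <- classify_events(detect_events_fluorescence(corrected))
        list(events = ev, bleach = attr(corrected, "bleach_fit"),
             truth = cl$truth)
      })
      stats <- area_stats(purrr::map(proc, "events"))
      list(per_cell = proc, area_stats = stats)
    }
  )
  out$config <- cfg
  if (!is.null(out_dir)) write_protocol_output(out, protocol, out_dir)
  out
}

interval_protocol <- function(mk, stim, reduced, seed, n_runs) {
  nr <- n_runs %||% if (reduced) 3 else 10
  conds <- fig3_conditions()
  if (reduced) conds <- conds[conds$level %in% c("low", "high") &
                                conds$conductance == "g_kdr", ]
  res <- purrr::pmap(conds, function(conductance, level, value) {
    m <- mk("fig3_7")
    m$par[[conductance]] <- value
    ie <- interval_experiment(m, stim, n_runs = nr,
                              seed = seed + 100 * which(
                                paste(conds$conductance, conds$level) ==
                                  paste(conductance, level)))
    key <- tibble::tibble(conductance = conductance, level = level,
                          value = value)
    prob <- if (is.null(ie$probability)) NULL else
      dplyr::bind_cols(key[rep(1, nrow(ie$probability)), ], ie$probability)
    list(prob = prob, n_events = nrow(ie$events))
  })
  list(probability = dplyr::bind_rows(purrr::map(res, "prob")),
       n_events = purrr::map_int(res, "n_events"))
}

write_protocol_output <- function(out, protocol, out_dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("writing protocol output requires the jsonlite package",
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- Filter(function(x) is.data.frame(x), out)
  purrr::iwalk(tabs, function(tb, nm)
    utils::write.csv(tb, file.path(out_dir, paste0(protocol, "_", nm, ".csv")),
                     row.names = FALSE))
  jsonlite::write_json(out$config,
                       file.path(out_dir, paste0(protocol, "_config.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
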