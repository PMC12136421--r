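#' Simulate the stochastic CA1 model
#'
#' Integrates the model with a fixed-step Euler--Maruyama scheme. The
#' deterministic part is the full conductance-based right-hand side (see
#' [dstate_dt()]); at every step the somatic voltage additionally receives a
#' Gaussian increment of standard deviation \eqn{\sqrt{2 D \, dt}/C},
#' the discretization of the Langevin noise current \eqn{\sqrt{2D}\,\xi(t)}.
#' The initial condition is rest ([initial_state()]): \eqn{V = E_L}, gates at
#' \eqn{x_\infty(E_L)}, zero calcium.
#'
#' With `noise_d = 0` (set via the model, e.g. `ca1_model(..., noise_d = 0)`)
#' the trajectory is deterministic and independent of `seed`.
#'
#' @param model A [ca1_model()].
#' @param stim A stimulus tibble (see [stimulus]) or `NULL`.
#' @param duration Total simulated time, ms.
#' @param dt Integration step, ms (default 0.02).
#' @param discard Initial transient, ms, flagged for exclusion from analysis
#'   (samples are kept in the trace; downstream event detection drops them).
#' @param seed Integer RNG seed; `NULL` leaves the RNG state alone.
#' @param record_gates Also record gate and calcium time series.
#' @return A tibble of class `ca1_trace` with columns `time`, `v_soma`,
#'   (`v_dend`,) `i_stim`, (`ca` and gate columns), and attributes `dt`,
#'   `discard`, `duration`, `model`, `stimulus`, `seed`.
#' @examples
#' m <- ca1_model("fig1_2", noise_d = 0)
#' tr <- simulate_ca1(m, stim_step(1), duration = 500)
#' range(tr$v_soma)
#' @export
simulate_ca1 <- function(model, stim = NULL, duration = 4000, dt = 0.02,
                         discard = 100, seed = NULL, record_gates = FALSE) {
  stopifnot(inherits(model, "ca1_model"), dt > 0, duration > discard,
            discard >= 0)
  n <- round(duration / dt)
  time <- (seq_len(n) - 1) * dt
  i_soma <- make_stimulus(stim, time, "soma")
  i_dend <- make_stimulus(stim, time, "dend")
  if (!is.null(seed)) set.seed(seed)
  res <- sim_ca1_cpp(unname(model$par), i_soma, i_dend, dt,
                     unname(initial_state(model)), record_gates)
  out <- tibble::tibble(time = time, v_soma = res$v_soma)
  if (model$par[["n_comp"]] > 1) out$v_dend <- res$v_dend
  out$i_stim <- i_soma + i_dend
  if (record_gates) {
    out$ca <- res$ca
    g <- res$gates
    colnames(g) <- c("h", "n", "z", "b", "r", "c", "q", "t")
    out <- dplyr::bind_cols(out, tibble::as_tibble(g))
  }
  structure(out, dt = dt, discard = discard, duration = duration,
            model = model, stimulus = stim, seed = seed,
            class = c("ca1_trace", class(out)))
}

#' Run an ensemble of simulations
#'
#' Repeats [simulate_ca1()] with seeds `seed, seed + 1, ...` and otherwise
#' identical configuration.
#'
#' @inheritParams simulate_ca1
#' @param n_runs Number of runs (>= 1).
#' @param seed Base seed for the first run.
#' @return A list of `ca1_trace` tibbles.
#' @export
run_ensemble <- function(model, stim = NULL, n_runs = 10, seed = 1, ...) {
  stopifnot(n_runs >= 1)
  purrr::map(seq_len(n_runs) - 1L,
             function(k) simulate_ca1(model, stim, seed = seed + k, ...))
}
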