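#' Generate synthetic ejection traces from the theory
#'
#' Inverts the glued two-branch closed-form solution — the confined
#' `m(t) = N (1 + t/t0)^(-zeta1)` down to the stage boundary `m*`, then
#' the tail `m(t) = M0 (1 - t/tau_ej)^zeta2` — to produce event traces in
#' the same schema as the simulator, optionally with an exponential
#' nucleation delay and per-event lognormal noise.  These ensembles drive
#' the closed-loop regression suite: theory in, pipeline out, parameters
#' recovered.
#'
#' @param cond An [ejection_condition()].
#' @param params A [theory_params()].
#' @param n_runs Number of traces.
#' @param noise Lognormal sdlog applied multiplicatively to each dwell
#'   increment (0 = deterministic event times).
#' @param nucleation_mean Mean of the exponential nucleation delay added
#'   before the ejection proper (0 = none).
#' @param Lp Pore length recorded in the trace header (sets the critical
#'   nucleus size downstream).
#' @param n_samples Number of `(t, m)` samples stored per trace.
#' @return An [ejection_ensemble()] with `provenance = "synthetic"`.
#' @examples
#' cond <- ejection_condition(N = 64, phi0 = 0.4)
#' ens <- synthesize_traces(cond, n_runs = 5, noise = 0.05)
#' @export
synthesize_traces <- function(cond, params = theory_params(), n_runs = 1,
                              noise = 0, nucleation_mean = 0, Lp = 1,
                              n_samples = 200) {
  stopifnot(inherits(cond, "ejection_condition"), inherits(params, "theory_params"))
  N <- as.integer(round(cond$N))
  base_times <- theory_event_times(cond, params)  # time of the j-th exit
  dwell <- diff(c(0, base_times))
  traces <- lapply(seq_len(n_runs), function(r) {
    dw <- dwell
    if (noise > 0) {
      dw <- dw * stats::rlnorm(N, meanlog = -noise^2 / 2, sdlog = noise)
    }
    delay <- if (nucleation_mean > 0) stats::rexp(1, 1 / nucleation_mean) else 0
    times <- delay + cumsum(dw)
    events <- tibble::tibble(
      time = times,
      bead = seq_len(N),
      dir = "out"
    )
    tau_total <- times[N]
    samp_t <- seq(0, tau_total, length.out = n_samples)
    samp_m <- N - findInterval(samp_t, times)
    ejection_trace(
      run_id = r, seed = NA_integer_,
      N = N, D = cond$D, phi0 = cond$phi0, Lp = Lp,
      events = events,
      samples = tibble::tibble(time = samp_t, m = samp_m),
      m0 = N, tau_total = tau_total,
      head_exit_time = delay, completed = TRUE,
      provenance = "synthetic"
    )
  })
  ejection_ensemble(traces)
}

# Exit times of the glued closed-form solution: entry j is the time at
# which m drops from N-j+1 to N-j (i.e. m(t_j) = N - j).
theory_event_times <- function(cond, params) {
  N <- as.integer(round(cond$N))
  ms <- m_star_effective(cond, params)
  t_ej <- ejection_time(cond, params)
  t0 <- confined_t0(cond, params)
  m_target <- N - seq_len(N)
  t_conf <- t0 * ((N / pmax(m_target, 1e-12))^(params$z1 - 1) - 1)
  t_tail <- t_ej - params$A2 * params$dt0 *
    m_target^(1 + params$z2) / (1 + params$z2)
  ifelse(m_target >= ms, t_conf, t_tail)
}
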