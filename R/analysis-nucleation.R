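#' Per-run nucleation times
#'
#' The nucleation (pre-ejection stall) time is read as a Kramers barrier
#' traversal: the run has nucleated once the heading `mn = ceiling(Lp/sigma)`
#' monomers fill the pore channel, i.e. once the cumulative net exits from
#' the cavity reach `mn` AND the head bead has passed the pore-exit plane.
#' In the no-barrier regime (`phi0 >= phi_p`, cavity osmotic pressure above
#' the in-pore pressure) the critical nucleus size is zero and `tau_n = 0`
#' by definition.
#'
#' Nucleation happens early in a run, so incomplete traces (step budget
#' exhausted mid-ejection) still contribute as long as they carry a
#' head-exit record; runs that never nucleated within their budget are
#' dropped.
#'
#' @param traces An [ejection_ensemble()]; traces carry `phi0` and `Lp`.
#' @param rp Effective pore radius used in the osmotic criterion.
#' @param sigma Monomer size.
#' @param require_complete Only use completed traces.
#' @return A tibble of class `nucleation_result` with per-run columns
#'   `run_id`, `tau_n`; attributes `tau_n_mean`, `tau_n_se`, `mn`,
#'   `barrier` (whether the osmotic criterion predicts a stall).
#' @export
nucleation_times <- function(traces, rp = 0.75, sigma = 1,
                             require_complete = FALSE) {
  if (require_complete) {
    traces <- completed_traces(traces)
  } else if (inherits(traces, "ejection_trace")) {
    traces <- list(traces)
  }
  tr1 <- traces[[1]]
  osm <- osmotic_pressures(rp = rp, phi0 = tr1$phi0, sigma = sigma)
  barrier <- osm$nucleation_expected
  mn <- if (barrier) as.integer(ceiling(tr1$Lp / sigma)) else 0L
  per_run <- purrr::map_dfr(traces, function(tr) {
    if (!barrier) {
      return(tibble::tibble(run_id = tr$run_id, tau_n = 0))
    }
    if (tr$completed && is.na(tr$head_exit_time)) {
      stop(sprintf("malformed trace (run %d): no head-exit record.", tr$run_id),
           call. = FALSE)
    }
    mt <- trace_m_of_t(tr)
    filled <- mt$time[tr$N - mt$m >= mn]
    if (is.na(tr$head_exit_time) || length(filled) == 0) {
      return(tibble::tibble(run_id = tr$run_id, tau_n = NA_real_))
    }
    tibble::tibble(run_id = tr$run_id,
                   tau_n = max(min(filled), tr$head_exit_time))
  })
  per_run <- per_run[!is.na(per_run$tau_n), ]
  if (nrow(per_run) == 0) {
    stop("no trace nucleated within its budget.", call. = FALSE)
  }
  attr(per_run, "tau_n_mean") <- mean(per_run$tau_n)
  attr(per_run, "tau_n_se") <-
    stats::sd(per_run$tau_n) / sqrt(nrow(per_run))
  attr(per_run, "mn") <- mn
  attr(per_run, "barrier") <- barrier
  class(per_run) <- c("nucleation_result", class(per_run))
  per_run
}

#' Trim the nucleation stage and normalize the ensemble m(t)
#'
#' Averages the step-function `m(t)` of the completed traces on a common
#' time grid, then removes the nucleation plateau by shifting time by
#' `<tau_n>` and the monomer count by the critical nucleus size `mn`, and
#' normalizes: `t_tilde = (t - <tau_n>)/<tau_ej>` and
#' `m_tilde = (<m> - mn)/(N - mn)`, with `<tau_ej> = <tau> - <tau_n>`.
#'
#' @param traces An [ejection_ensemble()].
#' @param nucleation A `nucleation_result` from [nucleation_times()];
#'   computed with defaults if missing.
#' @param n_grid Number of grid points spanning `t_tilde` in `[0, 1]`.
#' @return A tibble of class `trimmed_curve` with columns `time`
#'   (untrimmed), `m_mean`, `t_tilde`, `m_tilde`; attributes `tau_n`,
#'   `tau_ej`, `tau`, `mn`, `N`.
#' @export
trim_and_normalize <- function(traces, nucleation = nucleation_times(traces),
                               n_grid = 1000) {
  traces <- completed_traces(traces)
  N <- traces[[1]]$N
  tau <- mean(vapply(traces, function(tr) tr$tau_total, numeric(1)))
  tau_n <- attr(nucleation, "tau_n_mean")
  mn <- attr(nucleation, "mn")
  tau_ej <- tau - tau_n
  if (!is.finite(tau_ej) || tau_ej <= 0) {
    stop("degenerate ensemble: <tau_ej> must be positive.", call. = FALSE)
  }
  t_grid <- tau_n + seq(0, 1, length.out = n_grid) * tau_ej
  m_runs <- vapply(traces, function(tr) {
    trace_m_of_t(tr, times = t_grid)$m
  }, numeric(n_grid))
  m_mean <- rowMeans(m_runs)
  out <- tibble::tibble(
    time = t_grid,
    m_mean = m_mean,
    t_tilde = (t_grid - tau_n) / tau_ej,
    m_tilde = (m_mean - mn) / (N - mn)
  )
  attr(out, "tau_n") <- tau_n
  attr(out, "tau_ej") <- tau_ej
  attr(out, "tau") <- tau
  attr(out, "mn") <- mn
  attr(out, "N") <- N
  class(out) <- c("trimmed_curve", class(out))
  out
}

#' Ensemble mean m(t) on an arbitrary grid
#'
#' Untrimmed companion of [trim_and_normalize()], useful for plateau
#' diagnostics: left-step interpolation of each trace's event record on a
#' shared grid, averaged over completed runs.
#'
#' @param traces An [ejection_ensemble()].
#' @param times Time grid; defaults to 400 points up to the mean
#'   completion time.
#' @return A tibble with columns `time`, `m_mean`.
#' @export
ensemble_m_of_t <- function(traces, times = NULL) {
  traces <- completed_traces(traces)
  if (is.null(times)) {
    tau <- mean(vapply(traces, function(tr) tr$tau_total, numeric(1)))
    times <- seq(0, tau, length.out = 400)
  }
  m_runs <- vapply(traces, function(tr) trace_m_of_t(tr, times = times)$m,
                   numeric(length(times)))
  m_runs <- matrix(m_runs, nrow = length(times))
  tibble::tibble(time = times, m_mean = rowMeans(m_runs))
}

#' Split the ejection into its confined and non-confined stages
#'
#' Per run, the confined-stage duration is the first-passage time to the
#' stage boundary `m*` minus the run's nucleation time, and the ejection
#' time is the completion time minus the nucleation time.  The reported
#' ratio `<tau1>/<tau_ej>` measures how much of the ejection is spent in
#' the pressure-driven stage.
#'
#' @param traces An [ejection_ensemble()].
#' @param m_star Stage boundary (theoretical `(D/sigma)^(1/nu)` or the
#'   detected minimum of the velocity profile).
#' @param nucleation Optional `nucleation_result`; defaults to
#'   [nucleation_times()] on the ensemble.
#' @return A one-row tibble with `tau1_mean`, `tau_ej_mean`, `ratio`
#'   (clipped to `[0, 1]`) and `n_runs`; per-run table in attribute
#'   `per_run`.
#' @export
stage_split <- function(traces, m_star, nucleation = nucleation_times(traces)) {
  traces <- completed_traces(traces)
  N <- traces[[1]]$N
  if (m_star > N) stop("`m_star` cannot exceed the chain length.", call. = FALSE)
  taun <- stats::setNames(nucleation$tau_n, nucleation$run_id)
  per_run <- purrr::map_dfr(traces, function(tr) {
    tn <- unname(taun[as.character(tr$run_id)])
    if (is.na(tn)) tn <- 0
    if (tr$m0 <= m_star) {
      t1 <- 0
    } else {
      mt <- trace_m_of_t(tr)
      hit <- mt$time[mt$m <= m_star]
      t1 <- if (length(hit) > 0) max(min(hit) - tn, 0) else NA_real_
    }
    tibble::tibble(run_id = tr$run_id,
                   tau1 = t1,
                   tau_ej = tr$tau_total - tn)
  })
  ratio <- mean(per_run$tau1) / mean(per_run$tau_ej)
  out <- tibble::tibble(
    tau1_mean = mean(per_run$tau1),
    tau_ej_mean = mean(per_run$tau_ej),
    ratio = min(max(ratio, 0), 1),
    n_runs = nrow(per_run)
  )
  attr(out, "per_run") <- per_run
  out
}
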