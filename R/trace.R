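#' Ejection trace objects
#'
#' An `ejection_trace` is the unit of analysis: the per-run record of every
#' crossing of the cavity-exit (pore-entrance) plane, together with sampled
#' `(t, m)` snapshots, where `m` is the number of monomers in the cavity.
#' Simulator output and theory-generated synthetic traces share this one
#' schema, so the analysis pipeline is agnostic to provenance.
#'
#' @param run_id Integer run identifier.
#' @param seed RNG seed used for the run.
#' @param N,D,phi0,Lp Condition of the run (`D = Inf` for the planar case).
#' @param events Tibble with columns `time`, `bead`, `dir` (`"out"` or
#'   `"back"`), ordered by time.
#' @param samples Tibble with columns `time`, `m`.
#' @param m0 Monomer count in the cavity at `t = 0`.
#' @param tau_total Completion time (time of the final crossing that left
#'   the cavity empty), or `NA` for an incomplete run.
#' @param head_exit_time Time at which the head bead first passed the
#'   pore-exit plane.
#' @param completed Logical completion flag.
#' @param provenance `"simulation"` or `"synthetic"`.
#' @return An object of class `ejection_trace`.
#' @export
ejection_trace <- function(run_id, seed, N, D, phi0, Lp, events, samples,
                           m0, tau_total, head_exit_time, completed,
                           provenance = "simulation") {
  events <- tibble::as_tibble(events)
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("time", "bead", "dir") %in% names(events)),
            all(c("time", "m") %in% names(samples)))
  if (is.unsorted(events$time)) {
    stop("event times must be non-decreasing.", call. = FALSE)
  }
  structure(list(
    run_id = as.integer(run_id), seed = as.integer(seed),
    N = as.integer(N), D = D, phi0 = phi0, Lp = Lp,
    events = events, samples = samples,
    m0 = as.integer(m0), tau_total = tau_total,
    head_exit_time = head_exit_time, completed = isTRUE(completed),
    provenance = provenance
  ), class = "ejection_trace")
}

#' @export
print.ejection_trace <- function(x, ...) {
  cat(sprintf(
    "<ejection_trace run %d (%s)> N = %d, D = %s, phi0 = %.4g, Lp = %g\n",
    x$run_id, x$provenance, x$N,
    if (is.infinite(x$D)) "Inf" else sprintf("%.4g", x$D), x$phi0, x$Lp))
  cat(sprintf("  %d events, m0 = %d, tau_total = %s, completed = %s\n",
              nrow(x$events), x$m0,
              if (is.na(x$tau_total)) "NA" else sprintf("%.4g", x$tau_total),
              x$completed))
  invisible(x)
}

#' Reconstruct m(t) from the event record
#'
#' Net bookkeeping: `m(t) = m0 - (#out events <= t) + (#back events <= t)`.
#'
#' @param trace An [ejection_trace()].
#' @param times Times at which to evaluate; defaults to the event times.
#' @return A tibble with columns `time` and `m`.
#' @export
trace_m_of_t <- function(trace, times = NULL) {
  stopifnot(inherits(trace, "ejection_trace"))
  ev <- trace$events
  if (is.null(times)) times <- ev$time
  step <- ifelse(ev$dir == "out", -1L, 1L)
  idx <- findInterval(times, ev$time)
  cum <- c(0L, cumsum(step))
  tibble::tibble(time = times, m = trace$m0 + cum[idx + 1L])
}

#' Bundle traces into an ensemble
#'
#' @param traces A list of [ejection_trace()] objects from one condition.
#' @return An object of class `ejection_ensemble` (a list of traces).
#' @export
ejection_ensemble <- function(traces) {
  if (inherits(traces, "ejection_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1,
            all(vapply(traces, inherits, logical(1), "ejection_trace")))
  structure(traces, class = "ejection_ensemble")
}

#' @export
print.ejection_ensemble <- function(x, ...) {
  n_done <- sum(vapply(x, function(tr) tr$completed, logical(1)))
  cat(sprintf("<ejection_ensemble> %d traces (%d completed), N = %d\n",
              length(x), n_done, x[[1]]$N))
  invisible(x)
}

completed_traces <- function(traces) {
  if (inherits(traces, "ejection_trace")) traces <- list(traces)
  out <- Filter(function(tr) tr$completed, traces)
  if (length(out) == 0) {
    stop("no completed traces in the ensemble.", call. = FALSE)
  }
  out
}
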