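#' Waiting-time function W(m)
#'
#' For each monomer count `m`, the dwell time a run spends in the state
#' with exactly `m` monomers in the cavity, summed over recrossings
#' (cumulative dwell), then averaged over runs.  By construction the dwell
#' times of one run partition its processing time:
#' `sum_m W(m) = tau_total` exactly.
#'
#' @param traces An [ejection_ensemble()] (or list of traces); only
#'   completed traces contribute.
#' @return A tibble of class `waiting_time_table` with columns `m`,
#'   `W` (ensemble mean dwell), `se`, `n_runs`.  The per-run long table
#'   is attached as attribute `per_run`.
#' @examples
#' cond <- ejection_condition(N = 64, phi0 = 0.4)
#' tr <- synthesize_traces(cond, n_runs = 3)
#' waiting_times(tr)
#' @export
waiting_times <- function(traces) {
  traces <- completed_traces(traces)
  per_run <- purrr::map_dfr(traces, function(tr) {
    dw <- run_dwell_times(tr)
    dw$run_id <- tr$run_id
    dw
  })
  out <- per_run |>
    dplyr::group_by(.data$m) |>
    dplyr::summarise(
      W = mean(.data$W),
      se = stats::sd(.data$W) / sqrt(dplyr::n()),
      n_runs = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$m)
  attr(out, "per_run") <- per_run
  attr(out, "N") <- traces[[1]]$N
  class(out) <- c("waiting_time_table", class(out))
  out
}

# Dwell time per state m for one completed trace (cumulative over
# recrossings); the interval [0, first event) counts toward m0.
run_dwell_times <- function(tr) {
  ev <- tr$events
  if (nrow(ev) == 0) {
    return(tibble::tibble(m = integer(0), W = numeric(0)))
  }
  bounds <- c(0, ev$time)
  widths <- diff(c(bounds, tr$tau_total))
  # state during interval k is the value BEFORE event k
  step <- ifelse(ev$dir == "out", -1L, 1L)
  states <- tr$m0 + c(0L, cumsum(step))
  agg <- tapply(widths, states, sum)
  tibble::tibble(m = as.integer(names(agg)), W = as.numeric(agg)) |>
    dplyr::arrange(.data$m)
}

#' Empirical velocity profile from waiting times
#'
#' The mean ejection velocity at state `m` is the reciprocal of the mean
#' waiting time, `V(m) = sigma / <W(m)>`.  The stage boundary `m*` is
#' detected as the interior minimum of the profile after smoothing
#' `log V` with a centered 5-point moving window (refined to the raw
#' minimum within the smoothing half-window, since the smoothed argmin is
#' biased away from a sharp stage-boundary cliff); ties resolve to the
#' smallest `m`, and a profile whose smoothed minimum sits on the boundary
#' of the `m` grid is flagged monotone (`m_star_detected = NA`), the
#' signature of a chain below the critical length.
#'
#' @param table A `waiting_time_table` from [waiting_times()].
#' @param sigma Monomer size (sets velocity units).
#' @param smooth_window Width of the centered moving window (odd).
#' @return A tibble of class `velocity_profile_result` with columns `m`,
#'   `V`, `V_smooth`, `se`; attributes `m_star_detected`, `v_min` and
#'   `monotone`.
#' @export
velocity_profile_empirical <- function(table, sigma = 1, smooth_window = 5) {
  stopifnot(inherits(table, "waiting_time_table"), nrow(table) > 0)
  tab <- dplyr::filter(table, .data$m >= 1, .data$W > 0)
  v <- sigma / tab$W
  v_se <- sigma * tab$se / tab$W^2
  logv <- log(v)
  vs <- exp(moving_mean(logv, smooth_window))
  out <- tibble::tibble(m = tab$m, V = v, V_smooth = vs, se = v_se)
  i_min <- which(vs == min(vs))[1]  # ties -> smallest m (sorted ascending)
  # refine on the raw profile within the smoothing half-window: the
  # smoothed argmin is robust to noise but biased away from a sharp
  # stage-boundary cliff
  h <- (smooth_window - 1) %/% 2
  cand <- max(1L, i_min - h):min(length(v), i_min + h)
  i_min <- cand[which(v[cand] == min(v[cand]))[1]]
  monotone <- i_min == 1L || i_min == length(vs)
  attr(out, "m_star_detected") <- if (monotone) NA_integer_ else out$m[i_min]
  attr(out, "v_min") <- if (monotone) NA_real_ else out$V[i_min]
  attr(out, "monotone") <- monotone
  class(out) <- c("velocity_profile_result", class(out))
  out
}

moving_mean <- function(x, w) {
  h <- (w - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}
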