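# Shared fixtures: hand-constructed toy traces and small helpers.

# A trace with explicit event times; m0 beads in the cavity at t = 0.
toy_trace <- function(times, dirs = rep("out", length(times)), N = 5,
                      m0 = N, phi0 = 0.1, Lp = 1, tau_total = max(times),
                      head_exit_time = times[1], completed = TRUE) {
  ejection_trace(
    run_id = 1L, seed = 1L, N = N, D = (N / phi0)^(1 / 3), phi0 = phi0,
    Lp = Lp,
    events = tibble::tibble(time = times, bead = seq_along(times), dir = dirs),
    samples = tibble::tibble(time = 0, m = m0),
    m0 = m0, tau_total = tau_total, head_exit_time = head_exit_time,
    completed = completed, provenance = "synthetic"
  )
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}

# Random valid conditions on a reproducible grid (confined and not).
random_conditions <- function(n, seed = 421) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      N <- sample(4:2048, 1)
      phi0 <- stats::runif(1, 0.005, 0.5)
      ejection_condition(N = N, phi0 = phi0)
    })
  })
}
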