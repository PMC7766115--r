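p_def <- theory_params()

test_that("waiting times partition the processing time", {
  # constructed trace: m 5 -> 4 at t = 2, -> 3 at t = 5, -> ... -> 0 at 14
  tr <- toy_trace(times = c(2, 5, 9, 12, 14))
  wt <- waiting_times(tr)
  expect_equal(wt$W[wt$m == 5], 2)
  expect_equal(wt$W[wt$m == 4], 3)
  expect_equal(wt$W[wt$m == 3], 4)
  expect_equal(sum(wt$W), tr$tau_total)
  # recrossings accumulate dwell in the state where time is spent
  tr2 <- toy_trace(times = c(1, 2, 3, 4, 5, 6, 7),
                   dirs = c("out", "back", "out", "out", "out", "out", "out"),
                   N = 5)
  wt2 <- waiting_times(tr2)
  expect_equal(wt2$W[wt2$m == 5], 1 + 1)  # [0,1) and [2,3)
  expect_equal(wt2$W[wt2$m == 4], 1 + 1)  # [1,2) and [3,4)
  expect_equal(sum(wt2$W), tr2$tau_total)
  # exact partition across a stochastic ensemble
  set.seed(5)
  ens <- synthesize_traces(ejection_condition(N = 64, phi0 = 0.4), p_def,
                           n_runs = 5, noise = 0.3)
  per_run <- attr(waiting_times(ens), "per_run")
  sums <- tapply(per_run$W, per_run$run_id, sum)
  taus <- vapply(ens, function(x) x$tau_total, numeric(1))
  expect_equal(as.numeric(sums), taus, tolerance = 1e-12)
  expect_error(waiting_times(list()), "trace")
})

test_that("synthetic traces close the loop on the branch velocities", {
  cond <- ejection_condition(N = 128, phi0 = 0.4)
  ens <- synthesize_traces(cond, p_def, n_runs = 1, noise = 0)
  wt <- waiting_times(ens)
  # sigma/W(m) estimates the glued velocity on [m-1, m]; compare at the
  # midpoint, away from the stage boundary where the branch switches
  ms <- critical_values(cond, p_def)$m_star
  sel <- wt$m[wt$m > 2 & wt$m < 120 & abs(wt$m - 0.5 - ms) > 1.5]
  v_emp <- 1 / wt$W[match(sel, wt$m)]
  v_th <- polyeject:::glued_velocity(sel - 0.5, cond, p_def)
  expect_lt(max(abs(v_emp / v_th - 1)), 0.01)
})

test_that("velocity profile detection finds the stage boundary", {
  cond <- ejection_condition(N = 128, phi0 = 0.4)
  ms <- critical_values(cond, p_def)$m_star
  ens <- synthesize_traces(cond, p_def, n_runs = 1, noise = 0)
  vp <- velocity_profile_empirical(waiting_times(ens))
  # within one grid point of the brute-force minimum of the profile
  brute <- vp$m[which.min(vp$V)]
  expect_lte(abs(attr(vp, "m_star_detected") - brute), 1)
  expect_lt(abs(attr(vp, "m_star_detected") - ms), 2)
  expect_false(attr(vp, "monotone"))
  expect_equal(attr(vp, "v_min"), min(vp$V))
  # short chain (N < N*): monotone profile, boundary undefined
  cond_s <- ejection_condition(N = 24, D = 10)  # N* = 46
  vp_s <- velocity_profile_empirical(
    waiting_times(synthesize_traces(cond_s, p_def, n_runs = 1)))
  expect_true(attr(vp_s, "monotone"))
  expect_true(is.na(attr(vp_s, "m_star_detected")))
})

test_that("confined-branch rescaling collapses ensembles at equal phi0", {
  # multiplying V by N^(x1+z1)/m^z1 maps the confined branch onto the
  # constant dv0 phi0^z1/A1, independent of N and m
  set.seed(8)
  pooled <- unlist(lapply(c(64, 128, 256), function(N) {
    cond <- ejection_condition(N = N, phi0 = 0.4)
    ms <- critical_values(cond, p_def)$m_star
    ens <- synthesize_traces(cond, p_def, n_runs = 40, noise = 0.05)
    wt <- waiting_times(ens)
    sel <- wt$m > 1.3 * ms & wt$m < 0.9 * N
    v <- 1 / wt$W[sel]
    v * N^(p_def$x1 + p_def$z1) / (wt$m[sel] - 0.5)^p_def$z1
  }))
  expect_lt(stats::sd(pooled) / mean(pooled), 0.15)
})

test_that("nucleation times follow the Kramers/osmotic picture", {
  # constructed: head exits at t = 7, one net exit already -> tau_n = 7
  tr <- toy_trace(times = c(1, 7.5, 8), N = 5, phi0 = 0.1,
                  head_exit_time = 7)
  nt <- nucleation_times(tr)
  expect_equal(attr(nt, "mn"), 1L)
  expect_equal(nt$tau_n, 7)
  # mn = ceil(Lp): the channel must fill before nucleation completes
  tr3 <- toy_trace(times = c(1, 2, 3, 4, 5), N = 5, phi0 = 0.1, Lp = 3,
                   head_exit_time = 0.5)
  expect_equal(attr(nucleation_times(tr3), "mn"), 3L)
  expect_equal(nucleation_times(tr3)$tau_n, 3)
  # no barrier at phi0 >= phi_p: tau_n = 0 identically
  tr4 <- toy_trace(times = c(1, 2, 3, 4, 5), N = 5, phi0 = 0.4)
  expect_equal(nucleation_times(tr4)$tau_n, 0)
  # exponential delay recovered within 2 SE on a synthetic ensemble
  set.seed(21)
  # confined condition whose first dwell is short, so the delay dominates
  cond <- ejection_condition(N = 128, phi0 = 0.25)
  ens <- synthesize_traces(cond, p_def, n_runs = 500, nucleation_mean = 50)
  nt <- nucleation_times(ens)
  expect_lt(abs(attr(nt, "tau_n_mean") - 50), 2 * attr(nt, "tau_n_se") + 2)
})

test_that("trimming and normalization pin the curve ends", {
  cond <- ejection_condition(N = 256, phi0 = 0.4)
  ens <- synthesize_traces(cond, p_def, n_runs = 2, noise = 0)
  curve <- trim_and_normalize(ens)
  expect_equal(curve$m_tilde[1], 1, tolerance = 0.02)
  expect_equal(curve$t_tilde[1], 0)
  expect_equal(curve$t_tilde[nrow(curve)], 1)
  expect_lt(curve$m_tilde[nrow(curve)], 0.01)
  # an inserted nucleation stall is removed within grid resolution
  set.seed(31)
  cond2 <- ejection_condition(N = 256, phi0 = 0.1)
  base <- trim_and_normalize(synthesize_traces(cond2, p_def, n_runs = 1))
  stalled <- trim_and_normalize(
    synthesize_traces(cond2, p_def, n_runs = 200, nucleation_mean = 100))
  # compare m_tilde on the shared normalized grid
  idx <- seq(20, 960, by = 20)
  expect_lt(max(abs(stalled$m_tilde[idx] - base$m_tilde[idx])), 0.03)
})

test_that("stage fits recover the closed-form parameters", {
  # noiseless curve generated directly from the confined solution
  t <- seq(0, 400, length.out = 300)
  m <- 1000 * (1 + t / 100)^(-4)
  fit <- fit_confined(tibble::tibble(t = t, m = m), N = 1000)
  est <- tidy(fit)
  expect_equal(unname(est$estimate[est$term == "zeta1"]), 4, tolerance = 1e-4)
  expect_equal(unname(est$estimate[est$term == "t0"]), 100, tolerance = 1e-4)
  # noiseless tail
  tau_ej <- 500
  tt <- seq(300, 499, length.out = 200)
  mm <- 80 * (1 - tt / tau_ej)^0.45
  fit2 <- fit_nonconfined(tibble::tibble(t = tt, m = mm), tau_ej = tau_ej,
                          m_star = 160)
  est2 <- tidy(fit2)
  expect_equal(unname(est2$estimate[est2$term == "zeta2"]), 0.45, tolerance = 1e-4)
  expect_equal(unname(est2$estimate[est2$term == "M0"]), 80, tolerance = 1e-3)
  expect_true(glance(fit2)$isConv)
})

test_that("the pipeline recovers zeta1 and zeta2 from noisy ensembles", {
  set.seed(41)
  cond <- ejection_condition(N = 1024, phi0 = 0.4)
  ens <- synthesize_traces(cond, p_def, n_runs = 200, noise = 0.05)
  curve <- trim_and_normalize(ens)
  z1 <- tidy(fit_confined(curve))
  expect_lt(abs(z1$estimate[z1$term == "zeta1"] / p_def$zeta1 - 1), 0.1)
  ms <- critical_values(cond, p_def)$m_star
  z2 <- tidy(fit_nonconfined(curve, m_star = ms))
  expect_lt(abs(z2$estimate[z2$term == "zeta2"] / p_def$zeta2 - 1), 0.1)
})

test_that("fitted t0 scales as phi0^-z1 and N^(1+x1) across ensembles", {
  set.seed(51)
  t0_fit <- function(N, phi0) {
    cond <- ejection_condition(N = N, phi0 = phi0)
    ens <- synthesize_traces(cond, p_def, n_runs = 60, noise = 0.05)
    est <- tidy(fit_confined(trim_and_normalize(ens)))
    est$estimate[est$term == "t0"]
  }
  Ns <- c(128, 256, 512, 1024)
  sN <- fit_powerlaw(Ns, vapply(Ns, t0_fit, numeric(1), phi0 = 0.4))$exponent
  expect_lt(abs(sN / (1 + p_def$x1) - 1), 0.1)
  phis <- c(0.4, 0.2, 0.1, 0.05)
  sP <- fit_powerlaw(phis, vapply(phis, t0_fit, numeric(1), N = 512))$exponent
  expect_lt(abs(sP / (-p_def$z1) - 1), 0.1)
})

test_that("power-law fitting is exact on exact data and unbiased on noise", {
  fit <- fit_powerlaw(1:10, 7 * (1:10)^3)
  expect_equal(fit$exponent, 3, tolerance = 1e-12)
  expect_equal(fit$std.error, 0, tolerance = 1e-10)
  expect_equal(fit$prefactor, 7, tolerance = 1e-10)
  expect_error(fit_powerlaw(1:2, 1:2), "3")
  expect_error(fit_powerlaw(c(1, 2, 3), c(1, -2, 3)), "positive")
  # Monte Carlo: mean estimate over 1000 reps within 2 SE of the truth
  set.seed(61)
  x <- exp(seq(log(1), log(50), length.out = 20))
  est <- replicate(1000, {
    y <- x^2 * stats::rlnorm(20, sdlog = 0.01 * log(10))
    fit_powerlaw(x, y)$exponent
  })
  expect_lt(abs(mean(est) - 2), 2 * stats::sd(est) / sqrt(1000))
})

test_that("Kramers fits recover exponential barrier growth", {
  lps <- 1:5
  fit <- fit_kramers(lps, 2 * exp(0.5 * lps))
  expect_equal(fit$an, 2, tolerance = 1e-10)
  expect_equal(fit$bn, 0.5, tolerance = 1e-12)
  expect_error(fit_kramers(1:2, c(1, 2)), "3")
  expect_error(fit_kramers(1:3, c(1, -1, 2)), "positive")
  # bn decreases with phi0 and extrapolates to zero near phi_p when
  # dmu_cp is linear in (phi_p - phi0)
  phi_p <- osmotic_pressures(0.75, 0.4)$phi_p
  phis <- c(0.05, 0.1, 0.15, 0.2, 0.25)
  bns <- vapply(phis, function(phi0) {
    dmu <- 2.0 * (phi_p - phi0)
    fit_kramers(lps, kramers_nucleation_time(lps, dmu))$bn
  }, numeric(1))
  expect_true(all(diff(bns) < 0))
  root <- stats::lm(bns ~ phis)
  phi_root <- -stats::coef(root)[1] / stats::coef(root)[2]
  expect_lt(abs(phi_root - phi_p), 0.02)
})

test_that("stage split attributes the ejection to its two stages", {
  cond <- ejection_condition(N = 128, phi0 = 0.4)
  ens <- synthesize_traces(cond, p_def, n_runs = 3, noise = 0)
  # m* = N: the confined stage is empty
  expect_equal(stage_split(ens, m_star = 128)$ratio, 0)
  # m* = 1: essentially everything is confined
  expect_gt(stage_split(ens, m_star = 1)$ratio, 0.95)
  expect_error(stage_split(ens, m_star = 200), "exceed")
  # ratio is invariant under time-unit rescaling of the traces
  ms <- critical_values(cond, p_def)$m_star
  r1 <- stage_split(ens, ms)$ratio
  scaled <- ejection_ensemble(lapply(ens, function(tr) {
    tr$events$time <- tr$events$time * 1000
    tr$samples$time <- tr$samples$time * 1000
    tr$tau_total <- tr$tau_total * 1000
    tr$head_exit_time <- tr$head_exit_time * 1000
    tr
  }))
  expect_equal(stage_split(scaled, ms)$ratio, r1, tolerance = 1e-10)
  # closed loop: on theory traces the measured ratio equals tau1/tau_ej
  cond_l <- ejection_condition(N = 1024, phi0 = 0.4)
  ens_l <- synthesize_traces(cond_l, p_def, n_runs = 2)
  ms_l <- critical_values(cond_l, p_def)$m_star
  expected <- tau1(cond_l, p_def) / ejection_time(cond_l, p_def)
  expect_equal(stage_split(ens_l, ms_l)$ratio, expected, tolerance = 0.02)
})
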