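test_that("exponent algebra follows from the Flory exponent", {
  p <- theory_params(nu = 0.6)
  expect_equal(p$z1, 1.25)
  expect_equal(p$z2, 1.2)
  expect_equal(p$zeta1, 4)
  expect_equal(p$zeta2, 1 / 2.2)
  expect_equal(p$y2, 0.2)
  # nu = 0.5 (theta solvent): z1 = 2, z2 = 1
  p5 <- theory_params(nu = 0.5)
  expect_equal(p5$z1, 2)
  expect_equal(p5$z2, 1)
  expect_error(theory_params(nu = 1 / 3), "nu")
  expect_error(theory_params(nu = 0.7), "z1")  # z1 < 1: no confined stage
})

test_that("ejection conditions close over the phi0 = N (sigma/D)^3 identity", {
  c1 <- ejection_condition(N = 32, phi0 = 0.4)
  expect_equal(c1$D, 80^(1 / 3))
  c2 <- ejection_condition(N = 32, D = 80^(1 / 3))
  expect_equal(c2$phi0, 0.4)
  c3 <- ejection_condition(D = 80^(1 / 3), phi0 = 0.4)
  expect_equal(c3$N, 32)
  expect_error(ejection_condition(N = 32, D = 5, phi0 = 0.4), "inconsistent")
  expect_error(ejection_condition(N = 32, phi0 = 0.6), "phi0")
  expect_error(ejection_condition(N = 32), "two of")
})

test_that("critical values obey their power laws", {
  # nu = 1/2: m* = (D/sigma)^2
  cond <- ejection_condition(N = 30, D = 4)
  cv <- critical_values(cond, theory_params(nu = 0.5))
  expect_equal(cv$m_star, 16)
  # nu = 0.6, D = 10: frozen from log-domain evaluation exp(log(10)/0.6)
  cv6 <- critical_values(ejection_condition(N = 100, D = 10), theory_params())
  expect_equal(cv6$m_star, 46.4158883361278, tolerance = 1e-10)
  expect_equal(cv6$N_star, cv6$m_star)
  expect_equal(cv6$D_star, 100^0.6)
  expect_equal(cv6$phi_star, (1 / 10)^(1 / (1.25 * 0.6)))
  # m* = N exactly at the critical chain length
  p <- theory_params()
  condc <- ejection_condition(N = 46.4158883361278, D = 10)
  cvc <- critical_values(condc, p)
  expect_equal(cvc$m_star, condc$N, tolerance = 1e-12)
  expect_true(cvc$confined_possible)
  expect_false(critical_values(ejection_condition(N = 40, D = 10), p)$confined_possible)
})

test_that("velocity profile has the two stage asymptotics", {
  p <- theory_params()
  cond <- ejection_condition(N = 1e6, phi0 = 0.4)
  # entropic branch at small m: V -> dv0 * m^-z2 / A2
  m <- 2
  expect_rel_equal(velocity_profile(m, cond, p),
                   p$dv0 * m^(-p$z2) / p$A2, 1e-3)
  # pressure branch near m = N at high phi0: V -> dv0 phi^z1/(A1 N^x1)
  m <- cond$N
  phi <- m * (1 / cond$D)^3
  expect_rel_equal(velocity_profile(m, cond, p),
                   p$dv0 * phi^p$z1 / (p$A1 * cond$N^p$x1), 1e-2)
  expect_error(velocity_profile(0, cond, p), "positive")
  expect_error(velocity_profile(cond$N + 1, cond, p), "exceed")
})

test_that("velocity minimum tracks the stage boundary", {
  p <- theory_params()
  # brute-force integer minimization vs m* for several conditions
  for (N in c(128, 512, 2048)) {
    cond <- ejection_condition(N = N, phi0 = 0.4)
    ms <- critical_values(cond, p)$m_star
    m <- 1:N
    m_min <- m[which.min(velocity_profile(m, cond, p))]
    expect_gt(m_min, ms / 3)
    expect_lt(m_min, 3 * ms)
  }
  # the smooth two-term profile has its minimum at the velocity crossing,
  # scaling as D^(3 z1/(z1+z2)); verify the slope on a log grid of D
  N <- 256
  Ds <- exp(seq(log(8.5), log(20), length.out = 7))
  m_min <- vapply(Ds, function(D) {
    cond <- ejection_condition(N = N, D = D)
    m <- exp(seq(log(1), log(N), length.out = 4000))
    m[which.min(velocity_profile(m, cond, p))]
  }, numeric(1))
  slope <- fit_powerlaw(Ds, m_min)$exponent
  expect_equal(slope, 3 * p$z1 / (p$z1 + p$z2), tolerance = 0.02)
})

test_that("stage times match quadrature of the rate equations", {
  p <- theory_params()
  for (cond in list(ejection_condition(N = 100, phi0 = 0.4),
                    ejection_condition(N = 1024, phi0 = 0.1))) {
    ms <- critical_values(cond, p)$m_star
    # confined: dt = A1 * N^x1 * dt0 * m*^(1+z1) * m^-z1 dm
    q1 <- stats::integrate(function(m) {
      p$A1 * cond$N^p$x1 * p$dt0 * ms^(1 + p$z1) * m^(-p$z1)
    }, ms, cond$N, rel.tol = 1e-10)$value
    expect_rel_equal(tau1(cond, p), q1, 1e-8)
    # non-confined: dt = A2 * dt0 * m^z2 dm
    q2 <- stats::integrate(function(m) p$A2 * p$dt0 * m^p$z2,
                           0, ms, rel.tol = 1e-10)$value
    expect_rel_equal(tau2(cond, p), q2, 1e-8)
  }
  # N = N*: the confined stage vanishes
  condc <- ejection_condition(N = 46.4158883361278, D = 10)
  expect_equal(tau1(condc, p), 0)
  # short chain: tau2 covers the whole ejection with amplitude N
  conds <- ejection_condition(N = 20, D = 10)
  expect_equal(tau2(conds, p), p$A2 * p$dt0 * 20^(1 + p$z2) / (1 + p$z2))
})

test_that("confined-stage tau1 scales as N^(x1 + 2/(3 nu)) at fixed phi0", {
  # the subleading (m*/N)^(z1-1) correction decays slowly, so the
  # asymptotic slope is probed deep in the long-chain limit
  p <- theory_params()
  Ns <- 10^(12:15)
  t1 <- vapply(Ns, function(N) tau1(ejection_condition(N = N, phi0 = 0.4), p),
               numeric(1))
  slope <- fit_powerlaw(Ns, t1)$exponent
  expect_equal(slope, p$x1 + 2 / (3 * p$nu), tolerance = 0.01)
})

test_that("the three ejection-time parameterizations are identical", {
  p <- theory_params()
  for (cond in random_conditions(100)) {
    t_nd <- ejection_time(cond, p, "N_D")
    t_pn <- ejection_time(cond, p, "phi0_N")
    t_dp <- ejection_time(cond, p, "D_phi0")
    expect_rel_equal(c(t_pn, t_dp), c(t_nd, t_nd), 1e-9)
    expect_rel_equal(t_nd, tau1(cond, p) + tau2(cond, p), 1e-9)
  }
})

test_that("ejection time is continuous at the critical chain length", {
  p <- theory_params()
  D <- 10
  Nc <- critical_values(ejection_condition(N = 10, D = D), p)$N_star
  eps <- 1e-8
  t_lo <- ejection_time(ejection_condition(N = Nc * (1 - eps), D = D), p)
  t_hi <- ejection_time(ejection_condition(N = Nc * (1 + eps), D = D), p)
  expect_rel_equal(t_lo, t_hi, 1e-6)
  # at N = N* both pieces evaluate to the same pure-tail value
  t_at <- ejection_time(ejection_condition(N = Nc, D = D), p)
  expect_rel_equal(t_at, p$A2 * p$dt0 * Nc^(1 + p$z2) / (1 + p$z2), 1e-9)
})

test_that("confined m(t) solves the confined rate equation", {
  skip_if_not_installed("deSolve")
  p <- theory_params()
  cond <- ejection_condition(N = 1024, phi0 = 0.4)
  ms <- critical_values(cond, p)$m_star
  t1 <- tau1(cond, p)
  times <- seq(0, t1, length.out = 51)
  sol <- deSolve::ode(
    y = c(m = cond$N), times = times,
    func = function(t, y, parms) {
      list(-(1 / (p$A1 * cond$N^p$x1 * p$dt0)) * y[1]^p$z1 / ms^(1 + p$z1))
    }, rtol = 1e-10, atol = 1e-10
  )
  expect_rel_equal(m_of_t_confined(times, cond, p), sol[, "m"], 1e-6)
  expect_equal(m_of_t_confined(0, cond, p), cond$N)
  expect_rel_equal(m_of_t_confined(t1, cond, p), ms, 1e-9)
  expect_error(m_of_t_confined(-1, cond, p), "non-negative")
})

test_that("confined time constant t0 scales as phi0^-z1 N^(1+x1)", {
  p <- theory_params()
  t0_of <- function(N, phi0) {
    polyeject:::confined_t0(ejection_condition(N = N, phi0 = phi0), p)
  }
  Ns <- 2^(6:12)
  sN <- fit_powerlaw(Ns, vapply(Ns, t0_of, numeric(1), phi0 = 0.4))$exponent
  expect_equal(sN, 1 + p$x1, tolerance = 1e-6)
  phis <- 0.4 * 2^-(0:5)
  sP <- fit_powerlaw(phis, vapply(phis, t0_of, numeric(1), N = 512))$exponent
  expect_equal(sP, -p$z1, tolerance = 1e-6)
})

test_that("non-confined m(t) solves the tail rate equation", {
  skip_if_not_installed("deSolve")
  p <- theory_params()
  cond <- ejection_condition(N = 256, phi0 = 0.2)
  tej <- ejection_time(cond, p)
  expect_equal(m_of_t_nonconfined(tej, cond, p, tej), 0)
  # integrate Eq-5 dynamics backward from just before completion
  t_start <- 0.99 * tej
  m_start <- m_of_t_nonconfined(t_start, cond, p, tej)
  times <- seq(t_start, 0.2 * tej, length.out = 40)
  sol <- deSolve::ode(
    y = c(m = m_start), times = times,
    func = function(t, y, parms) list(-(1 / (p$A2 * p$dt0)) * y[1]^(-p$z2)),
    rtol = 1e-10, atol = 1e-10
  )
  expect_rel_equal(m_of_t_nonconfined(times, cond, p, tej), sol[, "m"], 1e-6)
  expect_error(m_of_t_nonconfined(tej * 1.01, cond, p, tej), "exceed")
  # M0 grows as tau_ej^zeta2
  tejs <- vapply(2^(6:10), function(N) {
    ejection_time(ejection_condition(N = N, phi0 = 0.2), p)
  }, numeric(1))
  M0s <- ((p$z2 + 1) * tejs / (p$A2 * p$dt0))^p$zeta2
  expect_equal(fit_powerlaw(tejs, M0s)$exponent, p$zeta2, tolerance = 1e-9)
})

test_that("osmotic pressures reproduce the pore/cavity criterion", {
  osm <- osmotic_pressures(rp = 0.75, phi0 = 0.4)
  expect_equal(round(osm$Pi_p, 3), 0.566)
  expect_equal(round(osm$Pi_c, 3), 0.764)
  expect_equal(round(osm$phi_p, 3), 0.296)
  expect_false(osm$nucleation_expected)  # Pi_c > Pi_p: imminent ejection
  expect_true(osmotic_pressures(rp = 0.75, phi0 = 0.2)$nucleation_expected)
  # the flag flips exactly at phi0 = phi_p
  expect_false(osmotic_pressures(rp = 0.75, phi0 = osm$phi_p)$nucleation_expected)
  expect_error(osmotic_pressures(rp = 0, phi0 = 0.4), "rp")
})

test_that("Kramers nucleation time is exponential in the barrier", {
  expect_equal(kramers_nucleation_time(Lp = 2, dmu_cp = 0), 1)  # sigma^2 eta/kT
  # doubling Lp squares the exponential factor
  t1 <- kramers_nucleation_time(Lp = 1.5, dmu_cp = 0.8)
  t2 <- kramers_nucleation_time(Lp = 3.0, dmu_cp = 0.8)
  expect_equal(t2, t1^2, tolerance = 1e-12)
  # log tau_n affine in Lp with slope dmu_cp/(sigma kT)
  lps <- 1:5
  fit <- stats::lm(log(kramers_nucleation_time(lps, dmu_cp = 0.37)) ~ lps)
  expect_equal(unname(stats::coef(fit)[2]), 0.37, tolerance = 1e-10)
  expect_error(kramers_nucleation_time(1, dmu_cp = -0.1), "non-negative")
})

test_that("full non-confined rate has the advertised limits and signs", {
  p <- theory_params()
  expect_equal(full_nonconfined_rate(5, 100, p, gamma_i = 1, gamma_o = 1), 0)
  # huge N: the bracket reduces to (1 - gamma_i)/m to high accuracy
  r <- full_nonconfined_rate(10, 1e6, p, gamma_i = 0, gamma_o = 0)
  bracket <- -r * p$A2 * 10^p$y2 * p$dt0
  expect_rel_equal(bracket, 1 / 10, 1e-4)
  # outward flow (negative rate) for small m when gamma_i < 1
  expect_lt(full_nonconfined_rate(2, 50, p, gamma_i = 0.5), 0)
  expect_error(full_nonconfined_rate(0, 10, p), "strictly between")
  expect_error(full_nonconfined_rate(10, 10, p), "strictly between")
})
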