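#' Theoretical ejection-velocity profile
#'
#' The instantaneous ejection velocity as a function of the number of
#' monomers `m` still in the cavity, combining the two stage mechanisms:
#'
#' * confined stage (`phi(m) = m (sigma/D)^3` above the overlap value):
#'   the chain is pressed out, `V1 = dv0 * phi(m)^z1 / (A1 * N^x1)`;
#' * non-confined stage: entropic pulling by the ejected segments,
#'   `V2 = dv0 * m^-z2 / A2`.
#'
#' The prefactors `A1`, `A2` act as stage frictions (they multiply the
#' stage times).  The profile is the sum `V1 + V2` of the two mechanisms,
#' which preserves both asymptotic scalings (`m^z1` at large `m`, `m^-z2`
#' at small `m`) and has a smooth interior minimum near the stage boundary
#' whenever the confined branch is expressed within `m <= N`.  The
#' departure velocity at `m = N` with `phi0` fixed falls off as `N^-x1`.
#'
#' @param m Monomer count(s) in the cavity; `1 <= m <= N` (real-valued
#'   arguments are accepted).
#' @param cond An [ejection_condition()]; `D = Inf` gives the pure
#'   non-confined profile.
#' @param params A [theory_params()].
#' @return A numeric vector of velocities in units of `sigma/dt0`.
#' @examples
#' cond <- ejection_condition(N = 256, phi0 = 0.4)
#' velocity_profile(c(5, 50, 200), cond)
#' @export
velocity_profile <- function(m, cond, params = theory_params()) {
  stopifnot(inherits(cond, "ejection_condition"), inherits(params, "theory_params"))
  if (any(m <= 0)) stop("`m` must be positive.", call. = FALSE)
  if (any(m > cond$N)) stop("`m` cannot exceed the chain length N.", call. = FALSE)
  phi <- m * (cond$sigma / cond$D)^3
  v1 <- params$dv0 * phi^params$z1 / (params$A1 * cond$N^params$x1)
  v2 <- params$dv0 * m^(-params$z2) / params$A2
  v1 + v2
}

#' Confined-stage ejection time
#'
#' Closed-form duration of the confined stage, obtained by integrating the
#' blob-pressure rate equation
#' `dm/dt = -(1/(A1*dt)) * m^z1 / m*^(1+z1)` (with `dt = N^x1 * dt0` the
#' pore-friction time) from `m = N` down to the stage boundary `m = m*`:
#'
#' `tau1 = A1 * dt0 * N^x1 / (z1 - 1) * (m*^2 - m*^(1+z1) * N^(1-z1))`
#'
#' For a short chain (`N <= N*`) the confined stage is absent and 0 is
#' returned.
#'
#' @inheritParams velocity_profile
#' @return Time in units of `dt0`.
#' @export
tau1 <- function(cond, params = theory_params()) {
  stopifnot(inherits(cond, "ejection_condition"), inherits(params, "theory_params"))
  if (abs(params$z1 - 1) < 1e-12) {
    stop("z1 = 1 is a degenerate exponent for the confined stage.", call. = FALSE)
  }
  ms <- (cond$D / cond$sigma)^(1 / params$nu)
  if (cond$N <= ms) return(0)
  N <- cond$N
  params$A1 * params$dt0 * N^params$x1 / (params$z1 - 1) *
    (ms^2 - ms^(1 + params$z1) * N^(1 - params$z1))
}

#' Non-confined-stage ejection time
#'
#' Closed-form duration of the entropy-driven tail stage, obtained by
#' integrating `dm/dt = -(1/(A2*dt0)) * m^-z2` from `min(m*, N)` down to 0:
#'
#' `tau2 = A2 * dt0 * min(m*, N)^(1+z2) / (1 + z2)`
#'
#' For a short chain (`N < N*`) this is the whole ejection.
#'
#' @inheritParams velocity_profile
#' @return Time in units of `dt0`.
#' @export
tau2 <- function(cond, params = theory_params()) {
  stopifnot(inherits(cond, "ejection_condition"), inherits(params, "theory_params"))
  ms <- m_star_effective(cond, params)
  params$A2 * params$dt0 * ms^(1 + params$z2) / (1 + params$z2)
}

#' Total ejection time
#'
#' `tau_ej = tau1 + tau2`, evaluated through any of the three equivalent
#' parameterizations of the condition: `(N, D)`, `(phi0, N)` or
#' `(D, phi0)`.  The three expressions are related by the identity
#' `phi0 = N (sigma/D)^3` and agree to relative tolerance 1e-9; the
#' function is continuous across the critical point `N = N*` (equivalently
#' `D = D*`, `phi0 = phi*`), where the confined piece vanishes.
#'
#' @inheritParams velocity_profile
#' @param parameterization Which pair of parameters to evaluate through.
#'   All are algebraically identical; exposing them separately allows the
#'   consistency of the pieces to be verified.
#' @return Time in units of `dt0`.
#' @examples
#' cond <- ejection_condition(N = 128, phi0 = 0.2)
#' ejection_time(cond)
#' @export
ejection_time <- function(cond, params = theory_params(),
                          parameterization = c("N_D", "phi0_N", "D_phi0")) {
  stopifnot(inherits(cond, "ejection_condition"), inherits(params, "theory_params"))
  parameterization <- match.arg(parameterization)
  z1 <- params$z1; z2 <- params$z2
  x1 <- params$x1; nu <- params$nu
  A1 <- params$A1; A2 <- params$A2; dt0 <- params$dt0
  tail_coef <- A2 / (1 + z2)
  head_coef <- A1 / (z1 - 1)

  switch(parameterization,
    N_D = {
      N <- cond$N; u <- cond$D / cond$sigma
      if (N < u^(1 / nu)) {
        dt0 * tail_coef * N^(1 + z2)
      } else {
        dt0 * (head_coef * N^x1 * (u^(2 / nu) - u^((1 + z1) / nu) * N^(1 - z1)) +
                 tail_coef * u^((1 + z2) / nu))
      }
    },
    phi0_N = {
      N <- cond$N; phi0 <- cond$phi0
      w <- N / phi0
      if (phi0 < N^(-1 / z1)) {
        dt0 * tail_coef * N^(1 + z2)
      } else {
        dt0 * (head_coef * N^x1 * (w^(2 / (3 * nu)) - w^z1 * N^(1 - z1)) +
                 tail_coef * w^((1 + z2) / (3 * nu)))
      }
    },
    D_phi0 = {
      u <- cond$D / cond$sigma; phi0 <- cond$phi0
      if (phi0 < u^(-1 / (z1 * nu))) {
        dt0 * tail_coef * (phi0 * u^3)^(1 + z2)
      } else {
        dt0 * (head_coef * (phi0 * u^3)^x1 *
                 (u^(2 / nu) - u^((1 + z1) / nu) * (u^3 * phi0)^(1 - z1)) +
                 tail_coef * u^((1 + z2) / nu))
      }
    }
  )
}

#' Monomer count vs time during the confined stage
#'
#' Closed-form solution of the confined-stage rate equation:
#' `m(t) = N * (1 + t/t0)^(-zeta1)` with
#' `t0 = zeta1 * A1 * m*^(1+z1) * N^(1-z1+x1) * dt0`, valid for
#' `0 <= t <= tau1` and satisfying `m(0) = N`, `m(tau1) = m*`.  The time
#' constant obeys the scaling `t0 = zeta1 * A1 * phi0^-z1 * N^(1+x1) * dt0`.
#'
#' @param t Time(s) since the start of the (trimmed) ejection, in `dt0`.
#' @inheritParams velocity_profile
#' @return Monomer count(s).
#' @export
m_of_t_confined <- function(t, cond, params = theory_params()) {
  stopifnot(inherits(cond, "ejection_condition"), inherits(params, "theory_params"))
  if (any(t < 0)) stop("`t` must be non-negative.", call. = FALSE)
  cond$N * (1 + t / confined_t0(cond, params))^(-params$zeta1)
}

confined_t0 <- function(cond, params) {
  ms <- (cond$D / cond$sigma)^(1 / params$nu)
  params$zeta1 * params$A1 * ms^(1 + params$z1) *
    cond$N^(1 - params$z1 + params$x1) * params$dt0
}

#' Monomer count vs time during the non-confined stage
#'
#' Closed-form tail solution `m(t) = M0 * (1 - t/tau_ej)^zeta2` with
#' `M0 = ((z2 + 1) * tau_ej / (A2 * dt0))^zeta2`, so that `m(tau_ej) = 0`.
#' Valid for `t <= tau_ej` (and physically for `m <= m*`).
#'
#' @param t Time(s) since the start of the (trimmed) ejection.
#' @param tau_ej Total ejection time; see [ejection_time()].
#' @inheritParams velocity_profile
#' @return Monomer count(s).
#' @export
m_of_t_nonconfined <- function(t, cond, params = theory_params(),
                               tau_ej = ejection_time(cond, params)) {
  stopifnot(inherits(params, "theory_params"))
  if (any(t > tau_ej)) stop("`t` cannot exceed tau_ej.", call. = FALSE)
  M0 <- ((params$z2 + 1) * tau_ej / (params$A2 * params$dt0))^params$zeta2
  M0 * (1 - t / tau_ej)^params$zeta2
}

#' Full non-confined rate equation
#'
#' The complete free-energy-balance rate for the non-confined stage,
#' including the entropic terms of the chain segments tethered inside and
#' outside the cavity and the trans-membrane chemical-potential bias:
#'
#' `dm/dt = -(1/(A2 * m^y2 * dt0)) * ((1-gamma_i)/m - (1-gamma_o)/(N-m) - dmu_io)`
#'
#' with `dmu_io` in units of `kB*T` and the `m^y2` factor carrying the
#' drift-friction correction of the residual coil.  For `N >> m` and
#' `dmu_io = 0` the leading term reduces to the `-m^-z2` scaling law used
#' by [tau2()] and [m_of_t_nonconfined()].
#'
#' @param m Monomer count, `0 < m < N`.
#' @param N Chain length.
#' @param params A [theory_params()].
#' @param gamma_i,gamma_o Surface-partition exponents of a chain tethered
#'   on the inner/outer side of the wall (free parameters).
#' @param dmu_io Chemical-potential difference per monomer, in `kB*T`.
#' @return `dm/dt` in units of `1/dt0` (negative when the chain flows out).
#' @export
full_nonconfined_rate <- function(m, N, params = theory_params(),
                                  gamma_i = 0, gamma_o = 0, dmu_io = 0) {
  stopifnot(inherits(params, "theory_params"))
  if (any(m <= 0) || any(m >= N)) {
    stop("`m` must lie strictly between 0 and N (poles at the ends).",
         call. = FALSE)
  }
  bracket <- (1 - gamma_i) / m - (1 - gamma_o) / (N - m) - dmu_io
  -bracket / (params$A2 * m^params$y2 * params$dt0)
}

# Velocity of the glued two-branch closed-form solution (what
# synthesize_traces encodes): V1 branch above m*, V2 branch below.
glued_velocity <- function(m, cond, params = theory_params()) {
  ms <- m_star_effective(cond, params)
  phi <- m * (cond$sigma / cond$D)^3
  v1 <- params$dv0 * phi^params$z1 / (params$A1 * cond$N^params$x1)
  v2 <- params$dv0 * m^(-params$z2) / params$A2
  ifelse(m >= ms, v1, v2)
}
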