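#' Scaling-theory parameter set
#'
#' Bundles the exponents and prefactors of the two-stage ejection theory.
#' The confined stage is governed by the blob-theory exponent
#' `z1 = 1/(3*nu - 1)` and a pore-friction exponent `x1` (friction grows as
#' `N^x1` through the characteristic time `dt = N^x1 * dt0`); the
#' non-confined stage by `z2 = 1 + y2` with `y2 = 2*nu - 1` arising from the
#' drift of the residual coil.  Derived quantities `zeta1 = 1/(z1 - 1)` and
#' `zeta2 = 1/(z2 + 1)` are the exponents of the closed-form m(t) solutions.
#'
#' All quantities are in reduced Lennard-Jones units: lengths in `sigma`,
#' energies in `kB*T = 1`, times in `dt0`.
#'
#' @param nu Flory exponent; 0.6 for a good-solvent coil in 3D.
#' @param x1 Pore-friction exponent (default 1/3, the 3D-to-1D geometric
#'   restriction at the pore).
#' @param y2 Non-confined friction exponent (default `2*nu - 1`).
#' @param A1,A2 Dimensionless stage prefactors promoting the scaling
#'   relations to equalities.
#' @param dt0 Characteristic time in time units.
#' @param sigma Monomer size in length units.
#' @return An object of class `theory_params`: a list carrying the inputs
#'   plus derived `z1`, `z2`, `zeta1`, `zeta2` and `dv0 = sigma/dt0`.
#' @examples
#' p <- theory_params(nu = 0.6)
#' p$z1   # 1.25
#' p$zeta1  # 4
#' @export
theory_params <- function(nu = 0.6, x1 = 1 / 3, y2 = 2 * nu - 1,
                          A1 = 0.04, A2 = 1.0, dt0 = 1, sigma = 1) {
  stopifnot(is.numeric(nu), length(nu) == 1L, is.finite(nu))
  if (nu <= 1 / 3) {
    stop("`nu` must exceed 1/3 so that z1 = 1/(3*nu - 1) is positive.",
         call. = FALSE)
  }
  if (A1 <= 0 || A2 <= 0) stop("prefactors A1, A2 must be positive.", call. = FALSE)
  if (dt0 <= 0 || sigma <= 0) stop("dt0 and sigma must be positive.", call. = FALSE)
  z1 <- 1 / (3 * nu - 1)
  z2 <- 1 + y2
  if (z1 <= 1) {
    stop("z1 = 1/(3*nu - 1) must exceed 1 (nu < 2/3) for a finite confined stage.",
         call. = FALSE)
  }
  structure(
    list(
      nu = nu, x1 = x1, y2 = y2,
      z1 = z1, z2 = z2,
      zeta1 = 1 / (z1 - 1), zeta2 = 1 / (z2 + 1),
      A1 = A1, A2 = A2,
      dt0 = dt0, sigma = sigma, dv0 = sigma / dt0
    ),
    class = "theory_params"
  )
}

#' @export
print.theory_params <- function(x, ...) {
  cat("<theory_params>\n")
  cat(sprintf("  nu = %.4g  x1 = %.4g  y2 = %.4g\n", x$nu, x$x1, x$y2))
  cat(sprintf("  z1 = %.4g  z2 = %.4g  zeta1 = %.4g  zeta2 = %.4g\n",
              x$z1, x$z2, x$zeta1, x$zeta2))
  cat(sprintf("  A1 = %.4g  A2 = %.4g  dt0 = %.4g  sigma = %.4g\n",
              x$A1, x$A2, x$dt0, x$sigma))
  invisible(x)
}

#' Ejection condition (N, D, phi0)
#'
#' An ejection experiment is specified by the chain length `N`, the cavity
#' diameter `D` and the initial volume fraction `phi0`, linked by
#' `phi0 = N * (sigma/D)^3`.  Supply exactly two; the third is computed.  If
#' all three are given they must satisfy the identity to relative tolerance
#' 1e-9.
#'
#' @param N Chain length (monomers).
#' @param D Cavity diameter in units of `sigma`.
#' @param phi0 Initial volume fraction of monomers in the cavity.
#' @param sigma Monomer size.
#' @return An object of class `ejection_condition` with fields `N`, `D`,
#'   `phi0`, `sigma`.
#' @examples
#' ejection_condition(N = 32, phi0 = 0.4)  # D = 80^(1/3)
#' @export
ejection_condition <- function(N = NULL, D = NULL, phi0 = NULL, sigma = 1) {
  given <- !vapply(list(N, D, phi0), is.null, logical(1))
  if (sum(given) < 2) {
    stop("supply at least two of N, D, phi0.", call. = FALSE)
  }
  if (is.null(phi0)) phi0 <- N * (sigma / D)^3
  if (is.null(D)) D <- sigma * (N / phi0)^(1 / 3)
  if (is.null(N)) N <- phi0 * (D / sigma)^3
  if (abs(phi0 - N * (sigma / D)^3) > 1e-9 * max(phi0, 1e-300)) {
    stop("N, D and phi0 are inconsistent: phi0 must equal N*(sigma/D)^3.",
         call. = FALSE)
  }
  if (N < 1) stop("N must be at least 1.", call. = FALSE)
  if (D <= sigma) stop("cavity diameter D must exceed sigma.", call. = FALSE)
  if (phi0 <= 0 || phi0 > 0.5) {
    stop("phi0 must lie in (0, 0.5] (phi_M = 0.5 is the packing ceiling).",
         call. = FALSE)
  }
  structure(list(N = N, D = D, phi0 = phi0, sigma = sigma),
            class = "ejection_condition")
}

#' @export
print.ejection_condition <- function(x, ...) {
  cat(sprintf("<ejection_condition> N = %g, D = %.6g sigma, phi0 = %.6g\n",
              x$N, x$D / x$sigma, x$phi0))
  invisible(x)
}

#' Critical values separating confined and non-confined ejection
#'
#' The two stages are demarcated by the monomer count
#' `m* = (D/sigma)^(1/nu)` at which the instantaneous volume fraction drops
#' to the overlap value `phi* = (sigma/D)^(1/(z1*nu))`.  Equivalently, a
#' chain shorter than `N* = (D/sigma)^(1/nu)` (or a cavity wider than
#' `D* = sigma*N^nu`) never feels the confinement and ejects through the
#' non-confined stage alone.
#'
#' @param cond An [ejection_condition()].
#' @param params A [theory_params()].
#' @return A one-row tibble with columns `m_star`, `N_star`, `D_star`,
#'   `phi_star` and the flag `confined_possible = (N >= N_star)`.
#' @examples
#' critical_values(ejection_condition(N = 32, phi0 = 0.4), theory_params())
#' @export
critical_values <- function(cond, params = theory_params()) {
  stopifnot(inherits(cond, "ejection_condition"), inherits(params, "theory_params"))
  s <- cond$sigma
  m_star <- (cond$D / s)^(1 / params$nu)
  tibble::tibble(
    m_star = m_star,
    N_star = m_star,
    D_star = s * cond$N^params$nu,
    phi_star = (s / cond$D)^(1 / (params$z1 * params$nu)),
    confined_possible = cond$N >= m_star
  )
}

# m* truncated to N: a short chain (N < N*) is entirely non-confined.
m_star_effective <- function(cond, params) {
  min((cond$D / cond$sigma)^(1 / params$nu), cond$N)
}
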