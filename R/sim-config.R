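#' Simulation configuration
#'
#' Assembles and validates the full parameter set of a Langevin-dynamics
#' ejection simulation in reduced LJ units (bead mass = 1, `kB*T` measured
#' in `eps`).  Geometry follows the wall-thickness convention: the 9-3 wall
#' reaches `kB*T` at a distance of about 0.75 `sigma`, so the nominal wall
#' sphere has diameter `DC = D + 0.5*sigma` for an effective cavity diameter
#' `D`, and the nominal pore cylinder radius is `dp_eff/2 + 0.25*sigma`.
#'
#' Supply `N` plus one of `D` or `phi0` (linked by `phi0 = N*(sigma/D)^3`),
#' or set `dinf = TRUE` for the infinite-cavity reference case (a tethered
#' coil on the cis side of a planar wall pierced by the pore).
#'
#' @param N Number of beads.
#' @param D Effective cavity diameter (`sigma` units).
#' @param phi0 Initial volume fraction; alternative to `D`.
#' @param dinf If `TRUE`, simulate the infinite-diameter geometry
#'   (no sphere; cis half-space bounded by a planar wall).
#' @param eps,sigma LJ interaction strength and length.
#' @param k_bond Harmonic bond constant (`eps/sigma^2`).
#' @param b0 Equilibrium bond length.
#' @param eps_w,sigma_w Wall 9-3 potential strength and length.
#' @param temp Thermostat temperature (`eps/kB`).
#' @param t_damp Langevin damping time (friction `gamma = 1/t_damp`).
#' @param dt Integration time step; must resolve the bond oscillation
#'   (`dt < 0.1*sqrt(m_bead/k_bond)`).
#' @param Lp Pore length (`sigma`).
#' @param dp_eff Effective pore diameter (`sigma`).
#' @param sample_interval Cadence of `(t, m)` samples during ejection.
#' @param max_time Integration budget per ejection run (reduced time).
#' @param seed Base RNG seed; run `r` uses `bitwXor(seed, r)`.
#' @param n_runs Default replicate count for [simulate_ejections()].
#' @return An object of class `sim_config` (a validated named list with
#'   derived geometry fields `DC`, `rp_nom`, `rp_eff`, `x_en`, `x_w`).
#' @examples
#' sim_config(N = 32, phi0 = 0.4)
#' @export
sim_config <- function(N, D = NULL, phi0 = NULL, dinf = FALSE,
                       eps = 1, sigma = 1, k_bond = 600, b0 = sigma,
                       eps_w = 3 * eps, sigma_w = sigma,
                       temp = 1.0, t_damp = 1.0, dt = 0.004,
                       Lp = 1.0, dp_eff = 1.5,
                       sample_interval = 0.5, max_time = 2e4,
                       seed = 1L, n_runs = 8L) {
  if (dinf) {
    D <- Inf
    phi0 <- 0
  } else {
    cond <- ejection_condition(N = N, D = D, phi0 = phi0, sigma = sigma)
    D <- cond$D
    phi0 <- cond$phi0
  }
  for (nm in c("eps", "sigma", "k_bond", "b0", "eps_w", "sigma_w", "temp",
               "t_damp", "dt", "Lp", "dp_eff", "sample_interval", "max_time")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0) {
      stop(sprintf("`%s` must be a single positive finite number.", nm),
           call. = FALSE)
    }
  }
  if (dt >= 0.1 * sqrt(1 / k_bond)) {
    stop(sprintf(
      "dt = %g does not resolve the bond oscillation; need dt < 0.1*sqrt(m/k) = %g.",
      dt, 0.1 * sqrt(1 / k_bond)), call. = FALSE)
  }
  rp_eff <- dp_eff / 2
  x_en <- if (dinf) 0 else D / 2
  cfg <- structure(list(
    N = as.integer(N), D = D, phi0 = phi0, dinf = dinf,
    eps = eps, sigma = sigma, k_bond = k_bond, b0 = b0,
    eps_w = eps_w, sigma_w = sigma_w,
    temp = temp, t_damp = t_damp, dt = dt,
    Lp = Lp, dp_eff = dp_eff, rp_eff = rp_eff,
    DC = if (dinf) Inf else D + 0.5 * sigma,
    rp_nom = rp_eff + 0.25 * sigma,
    x_en = x_en, x_w = x_en + Lp,
    sample_interval = sample_interval, max_time = max_time,
    seed = as.integer(seed), n_runs = as.integer(n_runs)
  ), class = "sim_config")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  if (x$dinf) {
    cat(sprintf("  N = %d, D = Inf (planar cis wall)\n", x$N))
  } else {
    cat(sprintf("  N = %d, D = %.4g, phi0 = %.4g\n", x$N, x$D, x$phi0))
  }
  cat(sprintf("  Lp = %g, dp_eff = %g (rp_eff = %g), dt = %g, T = %g, t_damp = %g\n",
              x$Lp, x$dp_eff, x$rp_eff, x$dt, x$temp, x$t_damp))
  invisible(x)
}

# Internal: geometry/potential lists handed to the C++ engine.
geom_list <- function(cfg) {
  list(
    dinf = cfg$dinf,
    Rc = if (cfg$dinf) Inf else cfg$DC / 2,
    x_en = cfg$x_en,
    x_w = cfg$x_w,
    x_pl = cfg$x_w - 0.25 * cfg$sigma,
    x_cis = cfg$x_en + 0.25 * cfg$sigma,
    rp_nom = cfg$rp_nom,
    sigma_w = cfg$sigma_w
  )
}

pot_list <- function(cfg) {
  list(eps = cfg$eps, sigma = cfg$sigma, k_bond = cfg$k_bond, b0 = cfg$b0,
       eps_w = cfg$eps_w, sigma_w = cfg$sigma_w)
}
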