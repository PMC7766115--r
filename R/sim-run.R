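#' Pair, bond and wall potentials
#'
#' Vectorized evaluators for the three interactions of the bead-spring
#' model, returning energy and the radial force `-dU/dr`:
#'
#' * `wca_energy_force()`: Weeks-Chandler-Andersen excluded volume (LJ 12-6
#'   truncated and shifted at `2^(1/6)*sigma`, purely repulsive);
#' * `bond_energy_force()`: harmonic bond `U = k/2 (b - b0)^2`;
#' * `wall_energy_force()`: LJ 9-3 wall
#'   `U = eps_w * ((2/15)(sigma_w/d)^9 - (sigma_w/d)^3)`, truncated and
#'   shifted to zero at its minimum `d = (2/5)^(1/6)*sigma_w` so it acts as
#'   a purely repulsive boundary.  With `eps_w = 3*eps` the wall reaches
#'   the thermal energy at `d` of about 0.75 `sigma`, the wall-thickness
#'   calibration behind the `DC = D + 0.5*sigma` geometry convention.
#'
#' @param r,b,d Distances (bead-bead, bond length, bead-wall).
#' @param eps,sigma,k,b0,eps_w,sigma_w Potential parameters.
#' @return A tibble with columns `energy` and `force`.
#' @export
wca_energy_force <- function(r, eps = 1, sigma = 1) {
  res <- wca_ef_cpp(r, eps, sigma)
  tibble::tibble(energy = res$energy, force = res$force)
}

#' @rdname wca_energy_force
#' @export
bond_energy_force <- function(b, k = 600, b0 = 1) {
  res <- bond_ef_cpp(b, k, b0)
  tibble::tibble(energy = res$energy, force = res$force)
}

#' @rdname wca_energy_force
#' @export
wall_energy_force <- function(d, eps_w = 3, sigma_w = 1) {
  res <- wall93_ef_cpp(d, eps_w, sigma_w)
  tibble::tibble(energy = res$energy, force = res$force)
}

#' Confinement force field
#'
#' Evaluates the piecewise wall field at arbitrary positions: inside the
#' sphere, the radial 9-3 force from the nominal wall sphere (exempting the
#' pore solid angle); inside the channel, the radial force from the nominal
#' cylinder; outside, the planar wall bounding the semi-space (with a hole
#' at the pore).  Along the pore axis the field is identically zero, so
#' the canonical transport path from cavity to semi-space is smooth.
#'
#' @param positions An `n x 3` matrix of bead positions.
#' @param config A [sim_config()].
#' @return A tibble with `energy` and force components `fx`, `fy`, `fz`.
#' @export
confinement_force <- function(positions, config) {
  stopifnot(inherits(config, "sim_config"))
  positions <- rbind(positions)
  res <- confinement_ef_cpp(positions, geom_list(config), pot_list(config))
  tibble::tibble(energy = res$energy,
                 fx = res$force[, 1], fy = res$force[, 2], fz = res$force[, 3])
}

new_chain_state <- function(positions, velocities = NULL, time = 0) {
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3)
  structure(list(positions = positions, velocities = velocities, time = time),
            class = "chain_state")
}

#' @export
print.chain_state <- function(x, ...) {
  cat(sprintf("<chain_state> %d beads, t = %.4g\n", nrow(x$positions), x$time))
  invisible(x)
}

#' Count the monomers in the cavity
#'
#' A bead is in the cavity iff its axial coordinate is strictly on the
#' cavity side of the pore-entrance plane; beads inside the channel (or
#' exactly on the plane) are outside, so the nucleation plateau ends with
#' `m` reduced by about `Lp/sigma`.
#'
#' @param state A `chain_state`.
#' @param config A [sim_config()].
#' @return Integer count.
#' @export
count_in_cavity <- function(state, config) {
  sum(state$positions[, 1] < config$x_en)
}

#' Advance the Langevin dynamics
#'
#' Runs `n_steps` of the BAOAB velocity-Verlet/Langevin integrator with
#' friction `gamma = m_bead/t_damp` and Gaussian noise satisfying
#' fluctuation-dissipation at the configured temperature.  Deterministic
#' given the R RNG state.  With `thermostat = FALSE` it reduces to plain
#' velocity-Verlet (symplectic, for energy-conservation checks).
#'
#' @param state A `chain_state`.
#' @param config A [sim_config()].
#' @param n_steps Number of integration steps.
#' @param thermostat Apply the Langevin friction/noise?
#' @param hold_head Freeze bead 1 (the head) in place?
#' @param fcap Optional cap on interaction-force magnitudes (soft
#'   push-off); non-positive disables.
#' @param confine_cavity Reflect all beads but the head at the entrance
#'   plane, keeping the chain in the cavity (loading/equilibration phases,
#'   where the held head blocks the pore).
#' @return The updated `chain_state` with diagnostic attributes
#'   `mean_kinetic_temp`, `max_bond`, `min_bond`.
#' @export
langevin_step <- function(state, config, n_steps = 1, thermostat = TRUE,
                          hold_head = FALSE, fcap = -1,
                          confine_cavity = FALSE) {
  stopifnot(inherits(state, "chain_state"), inherits(config, "sim_config"))
  res <- run_md_cpp(state$positions, state$velocities, state$time,
                    geom_list(config), pot_list(config),
                    config$temp, 1 / config$t_damp, config$dt, fcap,
                    as.numeric(n_steps), -1, thermostat, hold_head,
                    FALSE, FALSE, FALSE, confine_cavity)
  out <- new_chain_state(res$positions, res$velocities, res$time)
  attr(out, "mean_kinetic_temp") <- res$mean_kinetic_temp
  attr(out, "max_bond") <- res$max_bond
  attr(out, "min_bond") <- res$min_bond
  out
}

#' Load the chain into the cavity
#'
#' Produces a confined initial state at the configured volume fraction:
#' the head bead (index 1) is placed in the pore channel at the entrance
#' and the rest of the chain is grown bead by bead inside the cavity
#' (random unit steps of length `b0`, rejected outside the accessible
#' sphere), then relaxed with force-capped soft-core dynamics followed by
#' a short full-potential relaxation, with the head held fixed.  Bonded
#' topology is preserved throughout.  For `dinf` geometries the chain is
#' grown as a coil on the cis side of the planar wall.
#'
#' @param config A [sim_config()].
#' @param max_attempts Restarts allowed for the rejection growth.
#' @return A `chain_state` ready for [equilibrate()].
#' @export
pump_chain <- function(config, max_attempts = 200) {
  stopifnot(inherits(config, "sim_config"))
  N <- config$N
  s <- config$sigma
  head <- c(config$x_en + 0.05 * s, 0, 0)
  inside <- if (config$dinf) {
    function(p) p[1] <= config$x_en - 0.45 * s
  } else {
    rmax <- config$D / 2 - 0.45 * s
    if (rmax <= 0.3 * s) {
      stop("cavity too small to load the chain.", call. = FALSE)
    }
    function(p) sqrt(sum(p^2)) <= rmax
  }
  for (attempt in seq_len(max_attempts)) {
    pos <- matrix(NA_real_, N, 3)
    pos[1, ] <- head
    ok <- TRUE
    for (i in seq_len(N - 1) + 1) {
      placed <- FALSE
      for (try in 1:200) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        cand <- pos[i - 1, ] + config$b0 * u
        if (inside(cand)) {
          pos[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) break
    if (attempt == max_attempts) {
      stop("pumping timeout: failed to grow the chain into the cavity.",
           call. = FALSE)
    }
  }
  state <- new_chain_state(pos)
  # soft push-off: capped pair forces at a reduced time step
  soft <- config
  soft$dt <- config$dt / 4
  state <- langevin_step(state, soft, n_steps = 4000, hold_head = TRUE,
                         fcap = 50, confine_cavity = TRUE)
  # short full-potential relaxation
  state <- langevin_step(state, config, n_steps = 2000, hold_head = TRUE,
                         confine_cavity = TRUE)
  state$time <- 0
  state
}

#' Equilibrate the confined chain
#'
#' Evolves the loaded chain with the head bead held fixed at the pore
#' entrance for `duration` reduced time units (default `50*sqrt(N)`, long
#' compared to the confined chain's internal relaxation at these sizes).
#'
#' @param state A `chain_state` from [pump_chain()].
#' @param config A [sim_config()].
#' @param duration Equilibration length in reduced time units.
#' @return The equilibrated `chain_state` (time reset to 0), with the
#'   diagnostic attributes of [langevin_step()].
#' @export
equilibrate <- function(state, config, duration = 50 * sqrt(config$N)) {
  stopifnot(inherits(state, "chain_state"), inherits(config, "sim_config"))
  n_steps <- ceiling(duration / config$dt)
  out <- langevin_step(state, config, n_steps = n_steps, hold_head = TRUE,
                       confine_cavity = TRUE)
  out$time <- 0
  out
}

#' Run one ejection
#'
#' Releases the head-bead constraint and integrates until the last bead
#' crosses the pore-exit plane, recording every crossing of the
#' cavity-exit plane with its direction.  A one-sided reflection at the
#' entrance plane forbids the head bead from falling back into the cavity
#' until it has passed the pore exit (the no-return mechanism that
#' guarantees a successful ejection).  If the step budget
#' (`config$max_time`) is exceeded the trace is returned incomplete, with
#' `completed = FALSE`.
#'
#' @param state An equilibrated `chain_state`.
#' @param config A [sim_config()].
#' @param run_id,seed Identifiers stored in the trace header.
#' @return An [ejection_trace()].
#' @export
run_ejection <- function(state, config, run_id = 1L, seed = NA_integer_) {
  stopifnot(inherits(state, "chain_state"), inherits(config, "sim_config"))
  m0 <- count_in_cavity(state, config)
  res <- run_md_cpp(state$positions, state$velocities, 0,
                    geom_list(config), pot_list(config),
                    config$temp, 1 / config$t_damp, config$dt, -1,
                    ceiling(config$max_time / config$dt),
                    config$sample_interval, TRUE, FALSE,
                    TRUE, TRUE, TRUE, FALSE)
  events <- tibble::tibble(
    time = as.numeric(res$event_time),
    bead = as.integer(res$event_bead),
    dir = ifelse(res$event_dir > 0, "out", "back")
  )
  samples <- tibble::tibble(
    time = c(0, as.numeric(res$sample_time)),
    m = c(m0, as.integer(res$sample_m))
  )
  ejection_trace(
    run_id = run_id, seed = seed,
    N = config$N, D = config$D, phi0 = config$phi0, Lp = config$Lp,
    events = events, samples = samples, m0 = m0,
    tau_total = if (res$completed) res$completion_time else NA_real_,
    head_exit_time = res$head_exit_time,
    completed = res$completed,
    provenance = "simulation"
  )
}

#' Simulate an ensemble of ejection runs
#'
#' Full protocol per run -- load ([pump_chain()]), equilibrate
#' ([equilibrate()]), eject ([run_ejection()]) -- with per-run seed
#' `bitwXor(base_seed, run_id)` so the ensemble is reproducible and runs
#' are independent.
#'
#' @param config A [sim_config()].
#' @param n_runs Number of replicate runs (default `config$n_runs`).
#' @param base_seed Base seed (default `config$seed`).
#' @param equil_time Equilibration duration per run.
#' @return An [ejection_ensemble()].
#' @examples
#' \donttest{
#' cfg <- sim_config(N = 16, phi0 = 0.4, max_time = 2000)
#' ens <- simulate_ejections(cfg, n_runs = 2, base_seed = 7)
#' }
#' @export
simulate_ejections <- function(config, n_runs = config$n_runs,
                               base_seed = config$seed,
                               equil_time = 50 * sqrt(config$N)) {
  stopifnot(inherits(config, "sim_config"))
  traces <- lapply(seq_len(n_runs), function(r) {
    run_seed <- bitwXor(as.integer(base_seed), as.integer(r))
    set.seed(run_seed)
    state <- pump_chain(config)
    state <- equilibrate(state, config, duration = equil_time)
    run_ejection(state, config, run_id = r, seed = run_seed)
  })
  ejection_ensemble(traces)
}
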