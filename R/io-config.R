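#' Read a simulation/theory configuration file
#'
#' YAML configuration with up to five maps: `system` (N, D or phi0, dinf),
#' `potentials` (eps, sigma, k_bond, b0, eps_w, sigma_w), `protocol`
#' (temp, t_damp, dt, Lp, dp_eff, max_time), `output` (sample_interval,
#' seed, n_runs) and `theory` (nu, x1, y2, A1, A2, dt0).  Every omitted
#' key takes the model default; unknown keys fail fast with a message
#' naming the key.  Contradictory `N`, `D`, `phi0` triples are rejected.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `config` (a [sim_config()]) and `params`
#'   (a [theory_params()]).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `N:` key as the boolean FALSE; map it back
  if (!is.null(raw$system) && "FALSE" %in% names(raw$system)) {
    names(raw$system)[names(raw$system) == "FALSE"] <- "N"
  }
  known_sections <- c("system", "potentials", "protocol", "output", "theory")
  unknown <- setdiff(names(raw), known_sections)
  if (length(unknown) > 0) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  allowed <- list(
    system = c("N", "D", "phi0", "dinf"),
    potentials = c("eps", "sigma", "k_bond", "b0", "eps_w", "sigma_w"),
    protocol = c("temp", "t_damp", "dt", "Lp", "dp_eff", "max_time"),
    output = c("sample_interval", "seed", "n_runs"),
    theory = c("nu", "x1", "y2", "A1", "A2", "dt0")
  )
  for (sec in names(allowed)) {
    bad <- setdiff(names(raw[[sec]]), allowed[[sec]])
    if (length(bad) > 0) {
      stop(sprintf("unknown key(s) in [%s]: %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  sim_args <- c(raw$system, raw$potentials, raw$protocol, raw$output)
  if (is.null(sim_args$N)) {
    stop("config must provide system.N (plus one of D or phi0, or dinf).",
         call. = FALSE)
  }
  config <- do.call(sim_config, sim_args)
  params <- do.call(theory_params, raw$theory %||% list())
  list(config = config, params = params)
}

#' The simulation case grid
#'
#' The study lattice over chain length and packing: `N = 2^gN`,
#' `phi0 = 0.4 * 2^-gF`, hence `D = (2.5 * 2^(gN+gF))^(1/3) * sigma` and
#' the diameter generation satisfies `gD = gN + gF`.  Every generated case
#' obeys `phi0 = N (sigma/D)^3` exactly.
#'
#' @param gN,gF Integer vectors of generation numbers (the full grid of
#'   their combinations is produced).
#' @param sigma Monomer size.
#' @return A tibble with `gN`, `gF`, `gD`, `N`, `phi0`, `D` and the
#'   derived `N_star` column flagging the confinement regime.
#' @examples
#' grid_cases(gN = 4:6, gF = 0:2)
#' @export
grid_cases <- function(gN, gF, sigma = 1) {
  if (length(gN) == 0 || length(gF) == 0) {
    stop("generation ranges must be non-empty.", call. = FALSE)
  }
  tidyr::expand_grid(gN = as.integer(gN), gF = as.integer(gF)) |>
    dplyr::mutate(
      gD = .data$gN + .data$gF,
      N = 2^.data$gN,
      phi0 = 0.4 * 2^(-.data$gF),
      D = (2.5 * 2^.data$gD)^(1 / 3) * sigma,
      N_star = (.data$D / sigma)^(1 / 0.6),
      confined = .data$N >= .data$N_star
    )
}
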