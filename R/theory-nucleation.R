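#' Osmotic-pressure criterion for the nucleation stage
#'
#' Before sustained ejection starts, the heading monomers must traverse the
#' pore channel.  Whether this costs free energy is decided by comparing
#' the osmotic pressure of a monomer sitting in the channel,
#' `Pi_p = kBT / (pi * rp^2 * sigma)`, against the osmotic pressure of the
#' confined chain, `Pi_c = kBT * phi0 / ((pi/6) * sigma^3)` (the
#' denominator is the volume of a monomer of diameter `sigma`).  A
#' nucleation stall is expected when `Pi_c < Pi_p`, equivalently when
#' `phi0` is below the in-pore volume fraction
#' `phi_p = ((pi/6) * sigma^3) / (pi * rp^2 * sigma)`.
#'
#' @param rp Effective pore radius, in `sigma` units.
#' @param phi0 Initial volume fraction in the cavity.
#' @param sigma Monomer size.
#' @return A one-row tibble with `Pi_p`, `Pi_c`, `phi_p` (pressures in
#'   `kBT/sigma^3`) and the flag `nucleation_expected`.
#' @examples
#' osmotic_pressures(rp = 0.75, phi0 = 0.4)  # Pi_c > Pi_p: no stall
#' @export
osmotic_pressures <- function(rp, phi0, sigma = 1) {
  if (rp <= 0) stop("`rp` must be positive.", call. = FALSE)
  Pi_p <- 1 / (pi * rp^2 * sigma)
  Pi_c <- phi0 / ((pi / 6) * sigma^3)
  phi_p <- ((pi / 6) * sigma^3) / (pi * rp^2 * sigma)
  tibble::tibble(
    Pi_p = Pi_p,
    Pi_c = Pi_c,
    phi_p = phi_p,
    nucleation_expected = Pi_c < Pi_p
  )
}

#' Kramers estimate of the nucleation time
#'
#' The pre-ejection stall is read as a Kramers escape problem: the heading
#' `Lp/sigma` monomers must climb an activation barrier
#' `Ea = Lp * dmu_cp / sigma` (with `dmu_cp` the cavity-to-pore chemical
#' potential difference per monomer), giving
#'
#' `tau_n = (sigma^2 * eta / kBT) * exp(Lp * dmu_cp / (sigma * kBT))`
#'
#' monotone increasing in both `Lp` and `dmu_cp`; `log(tau_n)` is affine
#' in `Lp` with slope `dmu_cp/(sigma*kBT)`.
#'
#' @param Lp Pore length, in `sigma` units.
#' @param dmu_cp Chemical-potential difference per monomer (`kBT` units);
#'   must be non-negative.
#' @param eta Effective friction coefficient (reduced units).
#' @param kT Thermal energy (reduced units).
#' @param sigma Monomer size.
#' @return Nucleation time in reduced time units.
#' @export
kramers_nucleation_time <- function(Lp, dmu_cp, eta = 1, kT = 1, sigma = 1) {
  if (any(dmu_cp < 0)) stop("`dmu_cp` must be non-negative.", call. = FALSE)
  if (any(Lp <= 0)) stop("`Lp` must be positive.", call. = FALSE)
  (sigma^2 * eta / kT) * exp(Lp * dmu_cp / (sigma * kT))
}
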