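#' Fit the confined-stage solution to a trimmed curve
#'
#' Nonlinear least squares of `m = N (1 + t/t0)^(-zeta1)` to the starting
#' portion of a trimmed ensemble curve.  The fit window keeps the portion
#' with `m/N` between the window bounds (default `[0.4, 0.95]`): the upper
#' bound discards the departure transient, the lower bound stops well
#' above the stage boundary.
#'
#' @param curve A `trimmed_curve` from [trim_and_normalize()], or any
#'   tibble with columns `t` and `m` already shifted by the nucleation
#'   time and nucleus size.
#' @param N Amplitude of the solution (chain length, net of the nucleus
#'   size); taken from the curve attributes if absent.
#' @param window Fit window as a fraction of `N`, `c(low, high)`.
#' @return An object of class `stage_fit` carrying `zeta1`, `t0`, their
#'   standard errors, the window, and the underlying `nls` fit.
#' @export
fit_confined <- function(curve, N = NULL, window = c(0.4, 0.95)) {
  dat <- curve_data(curve)
  if (is.null(N)) N <- attr(curve, "N") - attr(curve, "mn")
  if (is.null(N)) stop("supply `N` (curve carries no chain length).", call. = FALSE)
  sel <- dat$m / N >= window[1] & dat$m / N <= window[2] & dat$t >= 0
  dat <- dat[sel, ]
  if (nrow(dat) < 5) stop("confined fit window contains too few points.", call. = FALSE)
  t0_init <- max(stats::median(dat$t), 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      m ~ N * (1 + t / t0)^(-zeta1),
      data = dat,
      start = list(zeta1 = 2, t0 = t0_init),
      lower = c(1e-3, 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop("confined-stage fit failed to converge: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  new_stage_fit(fit, stage = "confined", window = window, N = N)
}

#' Fit the non-confined tail solution to a trimmed curve
#'
#' Nonlinear least squares of `m = M0 (1 - t/tau_ej)^zeta2` to the
#' terminating portion of a trimmed ensemble curve, with `tau_ej` known
#' (the trimmed mean ejection time).  The fit window keeps
#' `m <= m_star * tail_fraction` (default half the stage boundary), fully
#' inside the entropy-driven stage.
#'
#' @param curve A `trimmed_curve` (or tibble with `t`, `m`).
#' @param tau_ej Total ejection time; from the curve attributes if absent.
#' @param m_star Stage boundary used to delimit the tail window.
#' @param tail_fraction Fraction of `m_star` defining the window top.
#' @return An object of class `stage_fit` carrying `zeta2`, `M0`.
#' @export
fit_nonconfined <- function(curve, tau_ej = NULL, m_star = NULL,
                            tail_fraction = 0.5) {
  dat <- curve_data(curve)
  if (is.null(tau_ej)) tau_ej <- attr(curve, "tau_ej")
  if (is.null(tau_ej)) stop("supply `tau_ej`.", call. = FALSE)
  if (is.null(m_star)) m_star <- max(dat$m)
  sel <- dat$m <= m_star * tail_fraction & dat$m > 0 & dat$t < tau_ej
  dat <- dat[sel, ]
  if (nrow(dat) < 5) stop("tail fit window contains too few points.", call. = FALSE)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      m ~ M0 * (1 - t / tau_ej)^zeta2,
      data = dat,
      start = list(zeta2 = 0.5, M0 = max(dat$m) * 2),
      lower = c(1e-3, 1e-12),
      upper = c(0.999, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop("non-confined-stage fit failed to converge: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  new_stage_fit(fit, stage = "nonconfined", window = tail_fraction, N = NULL)
}

curve_data <- function(curve) {
  if (inherits(curve, "trimmed_curve")) {
    tibble::tibble(
      t = curve$t_tilde * attr(curve, "tau_ej"),
      m = curve$m_tilde * (attr(curve, "N") - attr(curve, "mn"))
    )
  } else {
    stopifnot(all(c("t", "m") %in% names(curve)))
    tibble::as_tibble(curve[, c("t", "m")])
  }
}

new_stage_fit <- function(fit, stage, window, N) {
  est <- summary(fit)$coefficients
  structure(list(
    stage = stage,
    estimates = tibble::tibble(
      term = rownames(est),
      estimate = est[, "Estimate"],
      std.error = est[, "Std. Error"]
    ),
    window = window, N = N, fit = fit
  ), class = "stage_fit")
}

#' @export
print.stage_fit <- function(x, ...) {
  cat(sprintf("<stage_fit: %s>\n", x$stage))
  print(x$estimates)
  invisible(x)
}

stage_fit_value <- function(x, term) {
  x$estimates$estimate[x$estimates$term == term]
}

#' Power-law exponent by log-log least squares
#'
#' Unweighted ordinary least squares of `log10(y)` on `log10(x)`; the
#' slope is the scaling exponent, with its regression standard error, and
#' `10^intercept` the prefactor.
#'
#' @param x,y Positive numeric vectors (at least 3 points).
#' @return A one-row tibble of class `powerlaw_fit`: `exponent`,
#'   `std.error`, `prefactor`, `intercept`, `r_squared`, `n`.
#' @examples
#' fit_powerlaw(1:10, 7 * (1:10)^3)
#' @export
fit_powerlaw <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need at least 3 (x, y) points.", call. = FALSE)
  }
  if (any(x <= 0) || any(y <= 0)) {
    stop("power-law fitting needs strictly positive data.", call. = FALSE)
  }
  fit <- stats::lm(log10(y) ~ log10(x))
  sm <- summary(fit)
  out <- tibble::tibble(
    exponent = unname(stats::coef(fit)[2]),
    std.error = sm$coefficients[2, "Std. Error"],
    prefactor = 10^unname(stats::coef(fit)[1]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    n = length(x)
  )
  class(out) <- c("powerlaw_fit", class(out))
  out
}

#' Kramers fit of nucleation times vs pore length
#'
#' Least squares of `log(tau_n)` on `Lp` for the exponential model
#' `tau_n = an * exp(bn * Lp)`: `bn` is the slope (the per-length
#' activation `dmu_cp/(sigma kBT)`), `an = exp(intercept)` the attempt
#' prefactor.
#'
#' @param lp Pore lengths (at least 3).
#' @param tau_n Positive nucleation times.
#' @return A one-row tibble of class `kramers_fit`: `an`, `bn`, their
#'   standard errors, `r_squared`, `n`.
#' @examples
#' fit_kramers(1:5, 2 * exp(0.5 * (1:5)))
#' @export
fit_kramers <- function(lp, tau_n) {
  if (length(lp) != length(tau_n) || length(lp) < 3) {
    stop("need at least 3 pore lengths.", call. = FALSE)
  }
  if (any(tau_n <= 0)) {
    stop("Kramers fitting needs strictly positive nucleation times.",
         call. = FALSE)
  }
  fit <- stats::lm(log(tau_n) ~ lp)
  sm <- summary(fit)$coefficients
  out <- tibble::tibble(
    an = exp(unname(stats::coef(fit)[1])),
    bn = unname(stats::coef(fit)[2]),
    an_se = exp(unname(stats::coef(fit)[1])) * sm[1, "Std. Error"],
    bn_se = sm[2, "Std. Error"],
    r_squared = summary(fit)$r.squared,
    n = length(lp)
  )
  class(out) <- c("kramers_fit", class(out))
  out
}
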