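#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a stage fit
#'
#' One row per fitted parameter (`zeta1`/`t0` or `zeta2`/`M0`) with
#' estimate and standard error.
#'
#' @param x A `stage_fit` from [fit_confined()] or [fit_nonconfined()].
#' @param ... Unused.
#' @return A tibble with columns `stage`, `term`, `estimate`, `std.error`.
#' @export
tidy.stage_fit <- function(x, ...) {
  dplyr::mutate(x$estimates, stage = x$stage, .before = 1)
}

#' @rdname tidy.stage_fit
#' @export
glance.stage_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    stage = x$stage,
    sigma = s$sigma,
    finTol = s$convInfo$finTol %||% NA_real_,
    isConv = s$convInfo$isConv %||% TRUE,
    nobs = length(stats::residuals(x$fit))
  )
}

#' Tidy a power-law fit
#'
#' @param x A `powerlaw_fit` from [fit_powerlaw()].
#' @param ... Unused.
#' @return A two-row tibble (`exponent`, `intercept`) with estimates and
#'   standard errors.
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble::tibble(
    term = c("exponent", "intercept"),
    estimate = c(x$exponent, x$intercept),
    std.error = c(x$std.error, NA_real_)
  )
}

#' Tidy a Kramers fit
#'
#' @param x A `kramers_fit` from [fit_kramers()].
#' @param ... Unused.
#' @return A two-row tibble (`an`, `bn`) with estimates and standard
#'   errors.
#' @export
tidy.kramers_fit <- function(x, ...) {
  tibble::tibble(
    term = c("an", "bn"),
    estimate = c(x$an, x$bn),
    std.error = c(x$an_se, x$bn_se)
  )
}

#' Plot an empirical velocity profile
#'
#' Log-log profile of the ejection velocity versus the monomer count in
#' the cavity, with the smoothed curve and the detected stage boundary.
#' Read right to left to follow the time evolution.
#'
#' @param object A `velocity_profile_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.velocity_profile_result <- function(object, ...) {
  ms <- attr(object, "m_star_detected")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$m, y = .data$V)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$V_smooth), color = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "monomers in cavity m",
                  y = expression(V[ej] ~ (sigma / t[u])))
  if (!is.na(ms)) {
    p <- p + ggplot2::geom_vline(xintercept = ms, linetype = "dashed")
  }
  p
}

#' Plot a trimmed, normalized ensemble curve
#'
#' @param object A `trimmed_curve` from [trim_and_normalize()].
#' @param ... Unused.
#' @return A ggplot object of normalized monomer count vs normalized time.
#' @export
autoplot.trimmed_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_tilde, y = .data$m_tilde)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(tilde(t)), y = expression(tilde(m)))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the theoretical velocity profile for a condition
#'
#' @param cond An [ejection_condition()].
#' @param params A [theory_params()].
#' @param n_points Number of m values on the log grid.
#' @return A ggplot object.
#' @export
plot_velocity_theory <- function(cond, params = theory_params(),
                                 n_points = 200) {
  m <- exp(seq(log(1), log(cond$N), length.out = n_points))
  dat <- tibble::tibble(m = m, V = velocity_profile(m, cond, params))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$m, y = .data$V)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "monomers in cavity m",
                  y = expression(V[ej] ~ (sigma / t[u])))
}
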