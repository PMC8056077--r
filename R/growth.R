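#' Logistic seed-growth model
#'
#' Embryo growth is described by a logistic curve for relative seed mass,
#' \eqn{dm/dt = r\,m\,(1 - m/m_{cap})}. The specific growth rate
#' \eqn{\mu(t) = r\,(1 - m/m_{cap})} then falls from about 0.025 hr^-1 in the
#' earliest stages to about 0.0025 hr^-1 at the mature stage. The initial
#' mass fraction `f0` is chosen so that \eqn{\mu} hits `mu_mature` at
#' `t_mature_hr`.
#'
#' @param mu0 Early-development growth rate (hr^-1); also the logistic rate
#'   constant (the initial mass fraction is small, so \eqn{\mu(0) \approx r}).
#' @param mu_mature Growth rate at the mature stage (hr^-1).
#' @param t_mature_hr Time of the mature stage (hours).
#' @param mass_cap Mass ceiling (relative units).
#' @return An object of class `growth_model`.
#' @examples
#' g <- growth_model()
#' growth_curve(g, c(0, 432))$mu
#' @export
growth_model <- function(mu0 = 0.025, mu_mature = 0.0025, t_mature_hr = 360,
                         mass_cap = 1) {
  stopifnot(mu0 > mu_mature, mu_mature > 0)
  # solve f(t_mature) = 1 - mu_mature/r for the initial fraction f0
  r <- mu0
  f_m <- 1 - mu_mature / r
  a <- exp(-r * t_mature_hr)
  f0 <- f_m * a / (1 - f_m + f_m * a)
  structure(list(mu0 = mu0, r = r, f0 = f0, mass_cap = mass_cap,
                 mu_mature = mu_mature, t_mature_hr = t_mature_hr),
            class = "growth_model")
}

#' Seed mass and growth rate over time
#'
#' @param growth A [growth_model()].
#' @param t_hr Times (hours).
#' @return A list with numeric vectors `mass` and `mu` (hr^-1).
#' @export
growth_curve <- function(growth, t_hr) {
  stopifnot(inherits(growth, "growth_model"), all(t_hr >= 0))
  f0 <- growth$f0
  f <- f0 / (f0 + (1 - f0) * exp(-growth$r * t_hr))
  list(mass = growth$mass_cap * f, mu = growth$r * (1 - f))
}

#' @export
print.growth_model <- function(x, ...) {
  cat("Logistic growth model\n")
  cat(sprintf("  mu(0)      = %.4f hr^-1\n", growth_curve(x, 0)$mu))
  cat(sprintf("  mu(mature) = %.4f hr^-1 at %.0f hr\n",
              growth_curve(x, x$t_mature_hr)$mu, x$t_mature_hr))
  cat(sprintf("  initial mass fraction = %.3g\n", x$f0))
  invisible(x)
}
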