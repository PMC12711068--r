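#' The Inverse Weibull (Frechet-type) distribution
#'
#' Density, distribution function, quantile function, random generation,
#' cumulative hazard and inverse cumulative hazard for the Inverse Weibull
#' distribution in the canonical parameterization
#' \deqn{F(x) = \exp(-\phi x^{-\gamma}), \qquad x > 0,}
#' with tail parameter `phi` > 0 and shape `gamma` > 0. The density is
#' \eqn{f(x) = \phi \gamma x^{-(\gamma+1)} \exp(-\phi x^{-\gamma})} and the
#' cumulative hazard is \eqn{H(x) = -\log S(x) = -\log(1 - F(x))}.
#'
#' This heavy-tailed family (the mean is infinite for `gamma <= 1`) is the
#' standard choice for wear-out and extreme-degradation phenomena; every other
#' function in the package is expressed in this one parameterization. Users of
#' the scale--shape convention \eqn{F(x) = \exp(-(\lambda/x)^{\gamma})} can
#' convert with [iw_scale()] / [iw_from_scale()] (\eqn{\lambda = \phi^{1/\gamma}}).
#'
#' All tail computations use `log1p`/`expm1` compositions so that survival
#' probabilities and hazards remain accurate far into the upper tail, where
#' record values live. Arguments outside the support raise an error rather
#' than being clamped, so misuse inside samplers is caught early.
#'
#' @param x,q vector of positive quantiles.
#' @param p vector of probabilities in (0, 1).
#' @param n number of draws.
#' @param t vector of positive cumulative-hazard values.
#' @param phi positive tail parameter.
#' @param gamma positive shape parameter.
#' @param log,log.p logical; if `TRUE`, probabilities/densities are given as
#'   log values.
#' @param lower.tail logical; if `TRUE` (default) probabilities are
#'   \eqn{P(X \le x)}, otherwise \eqn{P(X > x)}.
#'
#' @return `dinvweibull` gives the density, `pinvweibull` the distribution
#'   function, `qinvweibull` the quantile function, `rinvweibull` random
#'   deviates, `cumhaz_invweibull` the cumulative hazard \eqn{H(x)} and
#'   `inv_cumhaz_invweibull` its inverse.
#'
#' @examples
#' dinvweibull(1, 1, 1)          # exp(-1)
#' pinvweibull(1, 1, 1)          # exp(-1)
#' qinvweibull(0.5, 1, 1)        # 1 / log(2)
#' cumhaz_invweibull(1, 1, 1)    # -log(1 - exp(-1))
#' @name invweibull
NULL

.check_iw_params <- function(phi, gamma) {
  if (any(!is.finite(phi)) || any(phi <= 0))
    stop("'phi' must be positive and finite", call. = FALSE)
  if (any(!is.finite(gamma)) || any(gamma <= 0))
    stop("'gamma' must be positive and finite", call. = FALSE)
  invisible(NULL)
}

.check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("'%s' must be positive and finite", name), call. = FALSE)
  invisible(NULL)
}

# log(1 - exp(-s)) for s > 0, accurate at both ends
.log1mexp <- function(s) {
  ifelse(s <= log(2), log(-expm1(-s)), log1p(-exp(-s)))
}

#' @rdname invweibull
#' @export
dinvweibull <- function(x, phi, gamma, log = FALSE) {
  .check_iw_params(phi, gamma)
  .check_positive(x, "x")
  ld <- log(phi) + log(gamma) - (gamma + 1) * log(x) - phi * x^(-gamma)
  if (log) ld else exp(ld)
}

#' @rdname invweibull
#' @export
pinvweibull <- function(q, phi, gamma, lower.tail = TRUE, log.p = FALSE) {
  .check_iw_params(phi, gamma)
  .check_positive(q, "q")
  lF <- -phi * q^(-gamma)             # log F, always <= 0
  if (lower.tail) {
    if (log.p) lF else exp(lF)
  } else {
    # S = 1 - exp(lF) = -expm1(lF), computed stably
    if (log.p) .log1mexp(-lF) else -expm1(lF)
  }
}

#' @rdname invweibull
#' @export
qinvweibull <- function(p, phi, gamma, lower.tail = TRUE, log.p = FALSE) {
  .check_iw_params(phi, gamma)
  lp <- if (log.p) p else log(p)
  if (!log.p && (any(p <= 0) || any(p >= 1)))
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  if (!lower.tail) lp <- .log1mexp(-lp)   # log(1 - p)
  if (any(!is.finite(lp)) || any(lp >= 0))
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  (-lp / phi)^(-1 / gamma)
}

#' @rdname invweibull
#' @export
rinvweibull <- function(n, phi, gamma) {
  .check_iw_params(phi, gamma)
  # -log(U) is standard exponential
  (stats::rexp(n) / phi)^(-1 / gamma)
}

#' @rdname invweibull
#' @export
cumhaz_invweibull <- function(x, phi, gamma) {
  .check_iw_params(phi, gamma)
  .check_positive(x, "x")
  # H = -log(1 - exp(-phi x^-gamma))
  -.log1mexp(phi * x^(-gamma))
}

#' @rdname invweibull
#' @export
inv_cumhaz_invweibull <- function(t, phi, gamma) {
  .check_iw_params(phi, gamma)
  .check_positive(t, "t")
  # H(x) = t  <=>  exp(-phi x^-gamma) = 1 - exp(-t)
  #        <=>  x = (-log(1 - exp(-t)) / phi)^(-1/gamma)
  (-.log1mexp(t) / phi)^(-1 / gamma)
}

#' Convert between canonical and scale--shape parameterizations
#'
#' The canonical form used throughout the package is
#' \eqn{F(x) = \exp(-\phi x^{-\gamma})}; the equivalent scale--shape form is
#' \eqn{F(x) = \exp(-(\lambda/x)^{\gamma})} with \eqn{\lambda = \phi^{1/\gamma}}.
#'
#' @param phi,gamma canonical parameters (both positive).
#' @param lambda positive scale parameter of the scale--shape form.
#' @return `iw_scale` returns the scale \eqn{\lambda}; `iw_from_scale` returns
#'   a named vector `c(phi, gamma)`.
#' @examples
#' iw_scale(8, 3)              # 2
#' iw_from_scale(2, 3)         # phi = 8, gamma = 3
#' @export
iw_scale <- function(phi, gamma) {
  .check_iw_params(phi, gamma)
  phi^(1 / gamma)
}

#' @rdname iw_scale
#' @export
iw_from_scale <- function(lambda, gamma) {
  .check_positive(lambda, "lambda")
  .check_positive(gamma, "gamma")
  c(phi = lambda^gamma, gamma = gamma)
}
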