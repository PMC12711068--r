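#' Candidate distributions for goodness-of-fit comparison
#'
#' Auxiliary density/distribution functions for the one-parameter inverse
#' exponential (`F(x) = exp(-rate/x)`; the Inverse Weibull with shape fixed
#' at 1) and the two-parameter log-logistic
#' (`F(x) = 1 / (1 + (x/scale)^(-shape))`), used by [gof_compare()].
#'
#' @param x,q positive quantiles.
#' @param rate positive rate of the inverse exponential.
#' @param scale,shape positive log-logistic parameters.
#' @param log,log.p,lower.tail as in the standard distribution functions.
#' @name gof-families
NULL

#' @rdname gof-families
#' @export
dinvexp <- function(x, rate, log = FALSE) {
  .check_positive(rate, "rate")
  .check_positive(x, "x")
  ld <- log(rate) - 2 * log(x) - rate / x
  if (log) ld else exp(ld)
}

#' @rdname gof-families
#' @export
pinvexp <- function(q, rate, lower.tail = TRUE, log.p = FALSE) {
  .check_positive(rate, "rate")
  .check_positive(q, "q")
  lF <- -rate / q
  if (lower.tail) { if (log.p) lF else exp(lF) }
  else { if (log.p) log(-expm1(lF)) else -expm1(lF) }
}

#' @rdname gof-families
#' @export
dllogis <- function(x, shape, scale, log = FALSE) {
  .check_positive(shape, "shape"); .check_positive(scale, "scale")
  .check_positive(x, "x")
  # logistic density of log x with location log(scale), scale 1/shape,
  # divided by x
  u <- shape * (log(x) - log(scale))
  ld <- log(shape) - log(x) + u - 2 * log1p(exp(u))
  if (log) ld else exp(ld)
}

#' @rdname gof-families
#' @export
pllogis <- function(q, shape, scale, lower.tail = TRUE, log.p = FALSE) {
  .check_positive(shape, "shape"); .check_positive(scale, "scale")
  .check_positive(q, "q")
  u <- shape * (log(q) - log(scale))
  p <- stats::plogis(u, lower.tail = lower.tail, log.p = log.p)
  p
}

.gof_families <- c("gamma", "weibull", "invweibull", "lnorm", "invexp",
                   "llogis")

#' Maximum-likelihood fit of a candidate family to i.i.d. positive data
#'
#' Fits one of six candidate distributions to an i.i.d. positive sample by
#' maximum likelihood (ordinary likelihood, not the record likelihood — this
#' is for raw application data such as degradation indices):
#' `gamma` and `weibull` via [fitdistrplus::fitdist()]; `lnorm` by
#' closed-form log-moments; `invweibull` by the exact reduction to a Weibull
#' fit on `1/x` (if \eqn{X} is Inverse Weibull(\eqn{\phi,\gamma}) then
#' \eqn{1/X} is Weibull with shape \eqn{\gamma} and scale
#' \eqn{\phi^{-1/\gamma}}); `invexp` in closed form
#' (\eqn{\hat{rate} = n / \sum 1/x_i}); `llogis` via a logistic fit to
#' `log(x)` ([MASS::fitdistr()]).
#'
#' @param x positive numeric sample, length >= 5.
#' @param family one of `"gamma"`, `"weibull"`, `"invweibull"`, `"lnorm"`,
#'   `"invexp"`, `"llogis"`.
#' @return A list of class `gof_fit`: `family`, `params` (named), `loglik`,
#'   `k` (number of parameters: 2, except `invexp`: 1), `cdf` (fitted
#'   distribution function), and `converged`.
#' @examples
#' x <- rinvweibull(200, 2, 3)
#' fit_candidate(x, "invweibull")
#' @export
fit_candidate <- function(x, family = .gof_families) {
  family <- match.arg(family)
  x <- as.numeric(x)
  if (length(x) < 5L || any(!is.finite(x)) || any(x <= 0))
    stop("'x' must be a positive sample of size >= 5", call. = FALSE)
  n <- length(x)
  res <- switch(family,
    gamma = {
      f <- fitdistrplus::fitdist(x, "gamma")
      list(params = f$estimate, loglik = f$loglik,
           cdf = function(q) stats::pgamma(q, f$estimate[["shape"]],
                                           rate = f$estimate[["rate"]]))
    },
    weibull = {
      f <- fitdistrplus::fitdist(x, "weibull")
      list(params = f$estimate, loglik = f$loglik,
           cdf = function(q) stats::pweibull(q, f$estimate[["shape"]],
                                             f$estimate[["scale"]]))
    },
    invweibull = {
      f <- fitdistrplus::fitdist(1 / x, "weibull")
      gam <- f$estimate[["shape"]]
      phi <- f$estimate[["scale"]]^(-gam)  # scale of 1/X is phi^(-1/gamma)
      est <- c(phi = phi, gamma = gam)
      list(params = est, loglik = sum(dinvweibull(x, phi, gam, log = TRUE)),
           cdf = function(q) pinvweibull(q, phi, gam))
    },
    lnorm = {
      ml <- mean(log(x))
      sl <- sqrt(mean((log(x) - ml)^2))
      est <- c(meanlog = ml, sdlog = sl)
      list(params = est,
           loglik = sum(stats::dlnorm(x, ml, sl, log = TRUE)),
           cdf = function(q) stats::plnorm(q, ml, sl))
    },
    invexp = {
      rate <- n / sum(1 / x)
      list(params = c(rate = rate),
           loglik = sum(dinvexp(x, rate, log = TRUE)),
           cdf = function(q) pinvexp(q, rate))
    },
    llogis = {
      f <- suppressWarnings(MASS::fitdistr(log(x), "logistic"))
      shape <- 1 / f$estimate[["scale"]]
      scale <- exp(f$estimate[["location"]])
      est <- c(shape = shape, scale = scale)
      list(params = est,
           loglik = sum(dllogis(x, shape, scale, log = TRUE)),
           cdf = function(q) pllogis(q, shape, scale))
    })
  structure(list(family = family, params = res$params, loglik = res$loglik,
                 k = if (family == "invexp") 1L else 2L, n = n,
                 cdf = res$cdf, converged = is.finite(res$loglik)),
            class = "gof_fit")
}

#' @export
print.gof_fit <- function(x, ...) {
  cat(sprintf("%s fit (k = %d), log-likelihood %.4f\n", x$family, x$k,
              x$loglik))
  print(x$params)
  invisible(x)
}

#' Empirical-distribution-function goodness-of-fit statistics
#'
#' Computes the Kolmogorov--Smirnov, Anderson--Darling and Cramer--von Mises
#' statistics from the probability integral transform
#' \eqn{u_{(i)} = F(x_{(i)})} of the sorted sample under the fitted CDF:
#' \deqn{KS = \max_i \max(i/n - u_{(i)},\; u_{(i)} - (i-1)/n)}
#' \deqn{CvM = \frac{1}{12n} + \sum_i \Big(u_{(i)} - \frac{2i-1}{2n}\Big)^2}
#' \deqn{AD = -n - \frac{1}{n}\sum_i (2i-1)\{\log u_{(i)} +
#'       \log(1 - u_{(n+1-i)})\}}
#' Transformed values of exactly 0 or 1 are clipped to machine-safe bounds
#' with a warning (they would otherwise make AD infinite). Statistic values
#' are reported, not p-values: with estimated parameters the asymptotic null
#' distributions do not apply.
#'
#' @param x numeric sample.
#' @param cdf fitted distribution function (vectorized).
#' @return Named vector `c(ks, ad, cvm)`.
#' @examples
#' x <- rinvweibull(100, 1, 2)
#' edf_stats(x, function(q) pinvweibull(q, 1, 2))
#' @export
edf_stats <- function(x, cdf) {
  n <- length(x)
  u <- sort(cdf(sort(as.numeric(x))))
  eps <- .Machine$double.xmin
  if (any(u <= 0) || any(u >= 1)) {
    warning("probability integral transform hit 0 or 1; clipping", call. = FALSE)
    u <- pmin(pmax(u, eps), 1 - .Machine$double.eps)
  }
  i <- seq_len(n)
  ks <- max(pmax(i / n - u, u - (i - 1) / n))
  cvm <- 1 / (12 * n) + sum((u - (2 * i - 1) / (2 * n))^2)
  ad <- -n - mean((2 * i - 1) * (log(u) + log1p(-u[n + 1 - i])))
  c(ks = ks, ad = ad, cvm = cvm)
}

#' Rank candidate distributions by goodness of fit
#'
#' Fits each candidate family to the sample ([fit_candidate()]) and reports
#' one row per family with the maximized log-likelihood, AIC
#' (\eqn{2k - 2\ell}), BIC (\eqn{k\log n - 2\ell}) and the KS, AD and CvM
#' statistics ([edf_stats()]), sorted by AIC (ties broken by BIC, then family
#' name). Families that fail to fit are kept in the table with `converged =
#' FALSE` and excluded from the ranking (sorted last).
#'
#' @param x positive numeric sample.
#' @param families character vector of families to compare (default all six).
#' @return A data frame of class `gof_table` with columns `family`, `k`,
#'   `loglik`, `aic`, `bic`, `ks`, `ad`, `cvm`, `converged`.
#' @examples
#' x <- rinvweibull(200, 2, 3)
#' gof_compare(x)
#' @export
gof_compare <- function(x, families = .gof_families) {
  families <- match.arg(families, .gof_families, several.ok = TRUE)
  n <- length(x)
  rows <- lapply(families, function(fam) {
    f <- tryCatch(fit_candidate(x, fam), error = function(e) NULL)
    if (is.null(f) || !f$converged)
      return(data.frame(family = fam, k = NA_integer_, loglik = NA_real_,
                        aic = NA_real_, bic = NA_real_, ks = NA_real_,
                        ad = NA_real_, cvm = NA_real_, converged = FALSE))
    st <- edf_stats(x, f$cdf)
    data.frame(family = fam, k = f$k, loglik = f$loglik,
               aic = 2 * f$k - 2 * f$loglik,
               bic = f$k * log(n) - 2 * f$loglik,
               ks = st[["ks"]], ad = st[["ad"]], cvm = st[["cvm"]],
               converged = TRUE)
  })
  out <- do.call(rbind, rows)
  ord <- order(!out$converged, out$aic, out$bic, out$family)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gof_table", "data.frame")
  out
}

#' @export
print.gof_table <- function(x, digits = 4L, ...) {
  y <- as.data.frame(x)
  ok <- y$converged
  mark <- function(col) {
    b <- rep("", nrow(y))
    if (any(ok)) b[ok][which.min(y[[col]][ok])] <- "*"
    b
  }
  y$best <- paste0(mark("aic"), mark("bic"), mark("ks"), mark("ad"),
                   mark("cvm"))
  print.data.frame(y, digits = digits, row.names = FALSE, ...)
  cat("(*: best per criterion among converged fits, aic-sorted)\n")
  invisible(x)
}
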