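#' Conditional density of a future record given the last observed record
#'
#' Given the n-th record \eqn{z = x_{u(n)}}, the m-th record
#' (\eqn{k = m - n} steps ahead) has conditional density
#' \deqn{g(y \mid z) = \frac{[H(y) - H(z)]^{k-1}}{\Gamma(k)}\,
#'       \frac{f(y)}{S(z)}, \qquad y > z,}
#' where \eqn{H = -\log S} is the cumulative hazard: the hazard increment
#' \eqn{H(y) - H(z)} is Gamma(k, 1) distributed. For `k = 1` this is the
#' parent density left-truncated at `z`. The density is zero for `y <= z`
#' (support), not an error.
#'
#' `rcond_record` draws from this density by the hazard construction:
#' \eqn{G \sim \mathrm{Gamma}(k, 1)}, \eqn{Y = H^{-1}(H(z) + G)}, so every
#' draw strictly exceeds `z`. Parameters `phi`, `gamma` may be vectors
#' (recycled against `nsim`), which is how posterior-predictive draws are
#' generated.
#'
#' @param y evaluation points (positive).
#' @param nsim number of draws.
#' @param z last observed record value (positive).
#' @param phi,gamma Inverse Weibull parameters.
#' @param k number of record steps ahead (`m - n`, integer >= 1).
#' @param log logical; return the log density.
#' @param seed optional integer seed.
#' @return `dcond_record`: density values; `rcond_record`: draws, all > `z`.
#' @examples
#' dcond_record(2, 1, 1, 1, k = 1)   # truncated parent density at y = 2
#' rcond_record(5, z = 2, phi = 1, gamma = 1, k = 3, seed = 1)
#' @export
dcond_record <- function(y, z, phi, gamma, k, log = FALSE) {
  if (length(k) != 1L || k < 1 || k != round(k))
    stop("'k' must be a positive integer", call. = FALSE)
  if (length(z) != 1L) stop("'z' must be a single record value", call. = FALSE)
  .check_positive(z, "z")
  .check_iw_params(phi, gamma)
  out <- rep(if (log) -Inf else 0, length.out = length(y))
  ok <- is.finite(y) & y > z
  if (any(ok)) {
    yk <- y[ok]
    hz <- cumhaz_invweibull(z, phi, gamma)
    dh <- cumhaz_invweibull(yk, phi, gamma) - hz
    # f(y)/S(z): log S(z) = -H(z)
    ld <- dinvweibull(yk, phi, gamma, log = TRUE) + hz - lgamma(k)
    if (k > 1) ld <- ld + (k - 1) * log(dh)
    out[ok] <- if (log) ld else exp(ld)
  }
  out
}

#' @rdname dcond_record
#' @export
rcond_record <- function(nsim, z, phi, gamma, k, seed = NULL) {
  if (any(k < 1) || any(k != round(k))) stop("'k' must be a positive integer",
                                             call. = FALSE)
  .check_positive(z, "z")
  .check_iw_params(phi, gamma)
  if (!is.null(seed)) set.seed(seed)
  g <- stats::rgamma(nsim, shape = k)
  inv_cumhaz_invweibull(cumhaz_invweibull(z, phi, gamma) + g, phi, gamma)
}

#' Predict future record values from a fitted model
#'
#' Predicts the m-th upper record (m > n) from an [iwrec] fit.
#'
#' For a Bayesian fit this is the Monte-Carlo form of the posterior
#' predictive density \eqn{g^*(y \mid x) = \int g(y \mid z, \phi, \gamma)\,
#' p(\phi, \gamma \mid x)\, d\phi\, d\gamma}: each retained posterior draw
#' contributes `draws_per` future-record draws from the conditional density
#' at the last observed record. For an MLE fit the same construction is used
#' with the parameters fixed at the MLE (a plug-in predictive). The point
#' predictor is the predictive mean and the conditional median is reported
#' alongside; note that for `gamma <= 1` the Inverse Weibull has no finite
#' mean, so the predictive mean can be very unstable while the median and
#' the equal-tailed interval remain well behaved.
#'
#' @param object an [iwrec] fit.
#' @param m index (or vector of indices) of the future record, each > n.
#' @param level predictive interval level.
#' @param draws_per future-record draws per posterior draw (Bayesian fit);
#'   for an MLE fit the total number of predictive draws is
#'   `draws_per * 10000`.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A data frame of class `iwrec_pred` with one row per `m`:
#'   columns `m`, `point` (predictive mean), `median` (conditional median),
#'   `lower`, `upper`, `level`.
#' @examples
#' r <- sim_records(10, 1, 1, seed = 7)
#' fit <- iwrec(r)
#' predict(fit, m = 12, seed = 1)
#' @export
predict.iwrec <- function(object, m, level = 0.95, draws_per = 1L,
                          seed = NULL, ...) {
  if (missing(m)) stop("'m' (future record index) is required", call. = FALSE)
  if (any(m <= object$n) || any(m != round(m)))
    stop("'m' must be an integer greater than the number of observed records",
         call. = FALSE)
  if (length(level) != 1L || level <= 0 || level >= 1)
    stop("'level' must be in (0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  z <- as.numeric(object$records)[object$n]
  a <- (1 - level) / 2
  rows <- lapply(sort(unique(as.integer(m))), function(mi) {
    k <- mi - object$n
    if (object$method == "bayes") {
      dm <- object$draws$draws
      if (draws_per > 1L)
        dm <- dm[rep(seq_len(nrow(dm)), each = draws_per), , drop = FALSE]
      y <- rcond_record(nrow(dm), z, dm[, 1L], dm[, 2L], k)
    } else {
      p <- object$coefficients
      y <- rcond_record(draws_per * 10000L, z, p[1L], p[2L], k)
    }
    q <- stats::quantile(y, c(a, 0.5, 1 - a), names = FALSE)
    data.frame(m = mi, point = mean(y), median = q[2L],
               lower = q[1L], upper = q[3L], level = level)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("iwrec_pred", "data.frame")
  out
}

#' @export
print.iwrec_pred <- function(x, digits = 5L, ...) {
  cat("Future record prediction (predictive mean, conditional median,",
      "equal-tailed interval)\n")
  print.data.frame(x, digits = digits, ...)
  invisible(x)
}

# predictive log-likelihood of (records, future record y at step k) and its
# analytic gradient wrt (phi, gamma, y); all n observed records enter in
# hazard form f/S since y lies beyond them
.pl_loglik <- function(x, y, phi, gamma, k) {
  z <- x[length(x)]
  if (y <= z) return(-Inf)
  lf <- dinvweibull(x, phi, gamma, log = TRUE)
  h <- cumhaz_invweibull(x, phi, gamma)
  dh <- cumhaz_invweibull(y, phi, gamma) - h[length(x)]
  sum(lf + h) + (k - 1) * log(dh) - lgamma(k) +
    dinvweibull(y, phi, gamma, log = TRUE)
}

.pl_grad <- function(x, y, phi, gamma, k) {
  # pieces for a vector of points
  piece <- function(v) {
    t <- v^(-gamma)
    S <- -expm1(-phi * t)               # survival
    FS <- exp(-phi * t) / S             # F/S
    list(t = t, lv = log(v),
         dH_phi = -t * FS,
         dH_gamma = phi * log(v) * t * FS,
         dlf_phi = 1 / phi - t,
         dlf_gamma = 1 / gamma - log(v) + phi * t * log(v))
  }
  z <- x[length(x)]
  px <- piece(x)
  py <- piece(y)
  hz <- cumhaz_invweibull(z, phi, gamma)
  hy <- cumhaz_invweibull(y, phi, gamma)
  dh <- hy - hz
  w <- if (k == 1) 0 else (k - 1) / dh
  d_phi <- sum(px$dlf_phi + px$dH_phi) +
    w * (py$dH_phi - px$dH_phi[length(x)]) + py$dlf_phi
  d_gamma <- sum(px$dlf_gamma + px$dH_gamma) +
    w * (py$dH_gamma - px$dH_gamma[length(x)]) + py$dlf_gamma
  hazard_y <- exp(dinvweibull(y, phi, gamma, log = TRUE) + hy)  # f(y)/S(y)
  d_y <- w * hazard_y - (gamma + 1) / y + phi * gamma * y^(-gamma - 1)
  c(d_phi, d_gamma, d_y)
}

#' Classical predictive-likelihood fit for a future record
#'
#' Jointly maximizes the predictive likelihood of Basak and Balakrishnan ---
#' the hazard-form likelihood of the n observed records, times
#' \eqn{[H(y) - H(x_{u(n)})]^{m-n-1}/\Gamma(m-n)}, times the parent density
#' at the future value \eqn{y} --- over \eqn{(\phi, \gamma, y)} subject to
#' \eqn{y > x_{u(n)}}. Optimization runs in
#' \eqn{(\log\phi, \log\gamma, \log(y - x_{u(n)}))} with the analytic
#' gradient, started from the record-sample MLE.
#'
#' For `m = n + 1` the profile over `y` is the mode of the left-truncated
#' parent density; when the last record already exceeds the parent mode (the
#' typical case for records) that mode sits on the boundary `y -> z+` and the
#' fitted `y` is reported just above the last record with
#' `boundary = TRUE`.
#'
#' @param x a [records] object or strictly increasing positive vector
#'   (n >= 2).
#' @param m future record index, > n.
#' @param start optional `c(phi, gamma)` start.
#' @param tol gradient-norm tolerance in the optimization coordinates.
#' @return A list with `coefficients` (`phi`, `gamma`), `predicted` (the
#'   maximizing `y`), `logLik`, `grad_norm`, `converged` and `boundary`.
#' @examples
#' r <- sim_records(10, 1, 1, seed = 3)
#' predict_record_pl(r, m = 13)
#' @export
predict_record_pl <- function(x, m, start = NULL, tol = 1e-6) {
  xv <- .as_record_values(x)
  n <- length(xv)
  if (n < 2L) stop("need at least 2 observed records", call. = FALSE)
  if (length(m) != 1L || m != round(m) || m <= n)
    stop("'m' must be a single integer greater than n", call. = FALSE)
  k <- m - n
  z <- xv[n]

  if (is.null(start)) {
    f0 <- .fit_record_mle(xv, restarts = 2L)
    start <- f0$par
  }
  # start y at the conditional median under the starting parameters
  y0 <- inv_cumhaz_invweibull(
    cumhaz_invweibull(z, start[1L], start[2L]) + stats::qgamma(0.5, k),
    start[1L], start[2L])
  th0 <- c(log(start[1L]), log(start[2L]), log(max(y0 - z, 1e-8 * z)))

  negf <- function(th) {
    v <- -.pl_loglik(xv, z + exp(th[3L]), exp(th[1L]), exp(th[2L]), k)
    if (!is.finite(v)) 1e10 else v
  }
  negg <- function(th) {
    p <- exp(th)
    g <- .pl_grad(xv, z + p[3L], p[1L], p[2L], k)
    -g * p
  }
  opt <- stats::optim(th0, negf, negg, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-14))
  # Nelder-Mead fallback + BFGS polish if the gradient is not flat yet
  gn <- sqrt(sum(negg(opt$par)^2))
  if (gn > tol) {
    opt2 <- stats::optim(opt$par, negf, control = list(maxit = 2000L,
                                                       reltol = 1e-14))
    opt3 <- stats::optim(opt2$par, negf, negg, method = "BFGS",
                         control = list(maxit = 500L, reltol = 1e-14))
    if (opt3$value < opt$value) opt <- opt3
    gn <- sqrt(sum(negg(opt$par)^2))
  }
  p <- unname(exp(opt$par))
  boundary <- p[3L] < 1e-6 * z   # maximizer pinned to the last record
  list(coefficients = c(phi = p[1L], gamma = p[2L]),
       predicted = z + p[3L], logLik = -opt$value, grad_norm = gn,
       converged = (gn < tol) || boundary, boundary = boundary,
       m = m, n = n)
}
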