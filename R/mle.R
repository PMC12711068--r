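#' Record-sample log-likelihood, score and observed information
#'
#' For an upper record sample \eqn{x_{u(1)} < \dots < x_{u(n)}} from the
#' Inverse Weibull distribution, the likelihood is the density of the last
#' record times the hazard contributions of the earlier ones,
#' \deqn{L(\phi,\gamma) = f(x_{u(n)}) \prod_{i=1}^{n-1}
#'       \frac{f(x_{u(i)})}{1 - F(x_{u(i)})},}
#' giving the log-likelihood
#' \deqn{\ell = n\log\phi + n\log\gamma - (\gamma+1)\sum \log x_{u(i)}
#'       - \phi \sum x_{u(i)}^{-\gamma}
#'       - \sum_{i=1}^{n-1}\log\{1 - e^{-\phi x_{u(i)}^{-\gamma}}\}.}
#' `score_records` returns the analytic gradient
#' \eqn{(\partial\ell/\partial\phi, \partial\ell/\partial\gamma)} and
#' `obsinfo_records` the observed information (negated analytic Hessian),
#' whose inverse at the MLE is the asymptotic covariance used for Wald limits.
#'
#' @param x a [records] object or strictly increasing positive numeric vector.
#' @param phi,gamma positive Inverse Weibull parameters.
#' @return `loglik_records`: a scalar. `score_records`: a named length-2
#'   vector. `obsinfo_records`: a symmetric 2x2 matrix.
#' @examples
#' r <- sim_records(20, 1, 1, seed = 1)
#' loglik_records(r, 1, 1)
#' score_records(r, 1, 1)
#' @export
loglik_records <- function(x, phi, gamma) {
  x <- .as_record_values(x)
  .check_iw_params(phi, gamma)
  n <- length(x)
  if (n < 1L) stop("record sample must be nonempty", call. = FALSE)
  lx <- log(x)
  t <- exp(-gamma * lx)                    # x^-gamma
  ll <- n * log(phi) + n * log(gamma) - (gamma + 1) * sum(lx) - phi * sum(t)
  if (n > 1L) {
    s <- phi * t[-n]
    # log(1 - e^{-s}); for s below underflow use log(s) computed in logs
    corr <- ifelse(s < 1e-8, log(phi) - gamma * lx[-n], .log1mexp(s))
    ll <- ll - sum(corr)
  }
  unname(ll)
}

#' @rdname loglik_records
#' @export
score_records <- function(x, phi, gamma) {
  x <- .as_record_values(x)
  .check_iw_params(phi, gamma)
  n <- length(x)
  lx <- log(x)
  t <- exp(-gamma * lx)
  d_phi <- n / phi - sum(t)
  d_gamma <- n / gamma - sum(lx) + phi * sum(t * lx)
  if (n > 1L) {
    lh <- lx[-n]
    # t F/(1-F) = t/expm1(phi t) -> 1/phi as phi t -> 0 (underflow guard)
    tr <- .t_ratio(t[-n], phi)
    d_phi <- d_phi - sum(tr)
    d_gamma <- d_gamma + phi * sum(lh * tr)
  }
  c(phi = d_phi, gamma = d_gamma)
}

# t F/(1-F) = t/(e^{phi t} - 1), with its phi*t -> 0 limit 1/phi
.t_ratio <- function(t, phi) {
  s <- phi * t
  ifelse(s < 1e-12, 1 / phi, t / expm1(s))
}

#' @rdname loglik_records
#' @export
obsinfo_records <- function(x, phi, gamma) {
  x <- .as_record_values(x)
  .check_iw_params(phi, gamma)
  n <- length(x)
  lx <- log(x)
  t <- exp(-gamma * lx)
  h_pp <- -n / phi^2
  h_pg <- sum(t * lx)
  h_gg <- -n / gamma^2 - phi * sum(t * lx^2)
  if (n > 1L) {
    th <- t[-n]
    lh <- lx[-n]
    s <- phi * th
    tr1 <- .t_ratio(th, phi)           # t F/(1-F), safe as s -> 0
    t2r2 <- tr1^2 * (1 + expm1(s))     # t^2 F/(1-F)^2 = (t F/(1-F))^2 e^s
    h_pp <- h_pp + sum(t2r2)
    h_pg <- h_pg + sum(lh * tr1) - phi * sum(lh * t2r2)
    h_gg <- h_gg - phi * sum(lh^2 * tr1) + phi^2 * sum(lh^2 * t2r2)
  }
  -matrix(c(h_pp, h_pg, h_pg, h_gg), 2L, 2L,
          dimnames = list(c("phi", "gamma"), c("phi", "gamma")))
}

# Safeguarded maximum-likelihood fit in (log phi, log gamma) space.
# Default start solves the phi score at gamma = 1 ignoring the record
# correction: phi0 = n / sum(1/x), gamma0 = 1.
.fit_record_mle <- function(x, start = NULL, tol = 1e-8, max_iter = 200L,
                            restarts = 5L) {
  x <- .as_record_values(x)
  n <- length(x)
  if (n < 2L)
    stop("record-sample MLE needs n >= 2 (the likelihood is unbounded at n = 1)",
         call. = FALSE)
  if (is.null(start)) start <- c(n / sum(1 / x), 1)

  negll <- function(theta) {
    v <- -loglik_records(x, exp(theta[1L]), exp(theta[2L]))
    if (!is.finite(v)) 1e10 else v
  }
  neggr <- function(theta) {
    p <- exp(theta)
    -score_records(x, p[1L], p[2L]) * p   # chain rule to log scale
  }

  polish <- function(theta) {
    # Newton on the log scale with step halving
    for (it in seq_len(max_iter)) {
      p <- exp(theta)
      sc <- score_records(x, p[1L], p[2L])
      g <- sc * p
      if (sqrt(sum(sc^2)) < tol) return(list(theta = theta, iter = it))
      Ii <- obsinfo_records(x, p[1L], p[2L])
      # Hessian on log scale: D I D - diag(g-ish); use damped solve
      H <- diag(p) %*% Ii %*% diag(p) - diag(g)
      step <- tryCatch(solve(H + diag(1e-10, 2L), g),
                       error = function(e) g)
      f0 <- negll(theta)
      s0 <- sqrt(sum(sc^2))
      lam <- 1
      repeat {
        cand <- theta + lam * step
        pc <- exp(cand)
        s1 <- sqrt(sum(score_records(x, pc[1L], pc[2L])^2))
        # near the optimum the objective decrease falls below rounding;
        # a shrinking score norm is the reliable progress measure there
        if (negll(cand) < f0 || s1 < s0) { theta <- cand; break }
        lam <- lam / 2
        if (lam < 1e-8) { theta <- theta + 1e-8 * step; break }
      }
    }
    list(theta = theta, iter = max_iter)
  }

  best <- NULL
  inits <- list(log(start))
  if (restarts > 0L) {
    jit <- lapply(seq_len(restarts), function(i) {
      log(start) + stats::runif(2L, -0.7, 0.7) * i / restarts
    })
    inits <- c(inits, jit)
  }
  for (ini in inits) {
    opt <- tryCatch(
      stats::optim(ini, negll, neggr, method = "BFGS",
                   control = list(maxit = max_iter, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) next
    pol <- polish(opt$par)
    p <- exp(pol$theta)
    sn <- sqrt(sum(score_records(x, p[1L], p[2L])^2))
    cand <- list(par = p, value = loglik_records(x, p[1L], p[2L]),
                 score_norm = sn, iter = pol$iter)
    if (is.null(best) || cand$value > best$value) best <- cand
    if (best$score_norm < tol) break
  }
  if (is.null(best))
    return(list(par = start, value = NA_real_, score_norm = Inf,
                iter = 0L, converged = FALSE, vcov = matrix(NA_real_, 2, 2)))

  info <- obsinfo_records(x, best$par[1L], best$par[2L])
  ev <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
  pd <- all(ev > 0)
  vc <- if (pd) solve(info) else matrix(NA_real_, 2L, 2L,
                                        dimnames = dimnames(info))
  if (pd) dimnames(vc) <- dimnames(info)
  list(par = c(phi = unname(best$par[1L]), gamma = unname(best$par[2L])),
       value = best$value, score_norm = best$score_norm, iter = best$iter,
       converged = (best$score_norm < tol) && pd, vcov = vc)
}
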