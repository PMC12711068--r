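# Independent numerical oracles used across the suite. These deliberately
# avoid the package's analytic code paths: finite differences for
# derivatives, trapezoid quadrature for posterior moments, grid search for
# optimizers.

fd_gradient <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- eps
    (f(x + e) - f(x - e)) / (2 * eps)
  }, numeric(1))
}

fd_hessian <- function(f, x, eps = 1e-4) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  for (j in seq_len(p)) for (k in seq_len(p)) {
    ej <- numeric(p); ej[j] <- eps
    ek <- numeric(p); ek[k] <- eps
    H[j, k] <- (f(x + ej + ek) - f(x + ej - ek) -
                f(x - ej + ek) + f(x - ej - ek)) / (4 * eps^2)
  }
  (H + t(H)) / 2
}

# log-grid search for the record-sample MLE, refined by derivative-free polish
grid_mle_oracle <- function(x, lo = 0.02, hi = 50, m = 400L) {
  lg <- seq(log(lo), log(hi), length.out = m)
  xv <- as.numeric(x)
  n <- length(xv)
  lx <- log(xv)
  best <- c(-Inf, NA, NA)
  for (lgam in lg) {
    gam <- exp(lgam)
    t <- exp(-gam * lx)
    phis <- exp(lg)
    # vectorized over phi at fixed gamma
    corr <- if (n > 1L) colSums(log(-expm1(-outer(t[-n], phis)))) else 0
    ll <- n * log(phis) + n * lgam - (gam + 1) * sum(lx) - phis * sum(t) - corr
    ll[!is.finite(ll)] <- -Inf
    j <- which.max(ll)
    if (is.finite(ll[j]) && ll[j] > best[1L]) best <- c(ll[j], phis[j], gam)
  }
  o <- stats::optim(log(best[2:3]),
                    function(th) -loglik_records(xv, exp(th[1]), exp(th[2])),
                    control = list(maxit = 2000, reltol = 1e-14))
  exp(o$par)
}

# trapezoid-rule posterior means over [lo, hi]^2
quadrature_posterior_mean <- function(x, prior, lo = 0.05, hi = 5, m = 240L) {
  g <- seq(lo, hi, length.out = m)
  lp <- outer(g, g, Vectorize(function(a, b) log_posterior(x, a, b, prior)))
  w <- exp(lp - max(lp))
  tw <- c(0.5, rep(1, m - 2L), 0.5)
  W <- outer(tw, tw)
  z <- sum(w * W)
  c(phi = sum(g * rowSums(w * W)) / z,
    gamma = sum(g * colSums(w * W)) / z)
}

ks_stat <- function(x, cdf) {
  u <- sort(cdf(sort(x)))
  n <- length(u)
  i <- seq_len(n)
  max(pmax(i / n - u, u - (i - 1) / n))
}

ks2_stat <- function(a, b) {
  unname(suppressWarnings(stats::ks.test(a, b)$statistic))
}
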