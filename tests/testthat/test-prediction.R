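test_that("k = 1 conditional density is the left-truncated parent density", {
  y <- c(1.2, 2, 5, 40)
  got <- dcond_record(y, z = 1, phi = 1.3, gamma = 0.9, k = 1)
  want <- dinvweibull(y, 1.3, 0.9) /
    pinvweibull(1, 1.3, 0.9, lower.tail = FALSE)
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(dcond_record(c(0.5, 1), z = 1, phi = 1, gamma = 1, k = 1),
               c(0, 0))
  expect_error(dcond_record(2, 1, 1, 1, k = 0), "positive integer")
})

test_that("the conditional density integrates to one beyond the last record", {
  for (zk in list(c(1, 1), c(1, 3), c(2, 2))) {
    I <- integrate(dcond_record, zk[1], Inf, z = zk[1], phi = 1, gamma = 1,
                   k = zk[2], rel.tol = 1e-9)$value
    expect_equal(I, 1, tolerance = 1e-6)
  }
})

test_that("future-record draws exceed the last record and match the density", {
  z <- 2
  y <- rcond_record(1e5, z, 1, 1, k = 3, seed = 8)
  expect_true(all(y > z))
  hz <- cumhaz_invweibull(z, 1, 1)
  # hazard increments are Gamma(k, 1)
  expect_lt(ks_stat(cumhaz_invweibull(y[1:10000], 1, 1) - hz,
                    function(q) pgamma(q, 3)), 0.02)
  # distribution-function form of the conditional density
  expect_lt(ks_stat(y[1:10000],
                    function(q) pgamma(cumhaz_invweibull(q, 1, 1) - hz, 3)),
            0.02)
  # k = 1: median hazard increment solves dH = log 2
  y1 <- rcond_record(20000, z, 1, 1, k = 1, seed = 9)
  dh <- cumhaz_invweibull(median(y1), 1, 1) - hz
  expect_lt(abs(dh - log(2)), 0.03)
})

test_that("Bayesian prediction: support, ordering in m, interval shape", {
  r <- sim_records(10, 1, 1, seed = 7)
  fit <- iwrec(r, method = "bayes", prior = iw_prior(3, 3, 3, 3),
               control = mcmc_control(4000, seed = 2))
  p <- predict(fit, m = c(11, 12, 15), seed = 4)
  z <- as.numeric(r)[10]
  expect_true(all(p$point > z))
  expect_true(all(p$median > z))
  expect_true(all(diff(p$median) > 0))
  expect_true(all(diff(p$lower) >= 0))
  expect_true(all(diff(p$upper) > 0))
  expect_true(all(p$lower < p$median & p$median < p$upper))
  expect_error(predict(fit, m = 10), "greater")
  # MLE plug-in path works too
  pm <- predict(iwrec(r), m = 11, seed = 5)
  expect_gt(pm$median, z)
})

test_that("a point-mass posterior reproduces the conditional density", {
  r <- sim_records(10, 1, 1, seed = 18)
  fit <- iwrec(r, method = "bayes", prior = iw_prior(3, 3, 3, 3),
               control = mcmc_control(4000, seed = 3))
  fit$draws$draws <- matrix(c(1.1, 0.9), nrow = 8000, ncol = 2, byrow = TRUE,
                            dimnames = list(NULL, c("phi", "gamma")))
  p <- predict(fit, m = 13, seed = 11)
  z <- as.numeric(r)[10]
  hz <- cumhaz_invweibull(z, 1.1, 0.9)
  # quantiles of the degenerate predictive match the conditional law exactly
  cond_q <- function(u) inv_cumhaz_invweibull(hz + qgamma(u, 3), 1.1, 0.9)
  expect_equal(p$median, cond_q(0.5), tolerance = 0.03)
  expect_equal(p$lower, cond_q(0.025), tolerance = 0.03)
  expect_equal(p$upper, cond_q(0.975), tolerance = 0.10)
})

test_that("classical predictive fit: constraint, stationarity, grid oracle", {
  r <- sim_records(20, 1, 1, seed = 9)
  z <- as.numeric(r)[20]
  pl <- predict_record_pl(r, m = 23)   # k = 3, interior optimum
  expect_gt(pl$predicted, z)
  expect_true(pl$converged)
  expect_lt(pl$grad_norm, 1e-6)
  # 3-D log-grid oracle over (phi, gamma, y - z), derivative-free polish
  gr <- function(lo, hi, m) exp(seq(log(lo), log(hi), length.out = m))
  best <- c(-Inf, NA, NA, NA)
  for (ph in gr(0.2, 8, 40)) for (ga in gr(0.3, 3, 40)) for (dy in gr(z * 1e-4, z * 50, 40)) {
    v <- iwrec:::.pl_loglik(as.numeric(r), z + dy, ph, ga, 3)
    if (v > best[1]) best <- c(v, ph, ga, dy)
  }
  o <- optim(log(best[2:4]), function(th)
    -iwrec:::.pl_loglik(as.numeric(r), z + exp(th[3]), exp(th[1]), exp(th[2]), 3),
    control = list(maxit = 5000, reltol = 1e-14))
  oracle <- exp(o$par)
  expect_equal(unname(pl$coefficients), oracle[1:2], tolerance = 1e-2)
  expect_equal(pl$predicted, z + oracle[3], tolerance = 1e-2 * pl$predicted)
  expect_error(predict_record_pl(r, m = 20), "greater")
})

test_that("analytic predictive-likelihood gradient matches finite differences", {
  r <- sim_records(12, 1, 1, seed = 25)
  x <- as.numeric(r)
  y <- x[12] * 3
  g <- iwrec:::.pl_grad(x, y, 1.2, 0.8, 4)
  fd <- fd_gradient(function(th) iwrec:::.pl_loglik(x, th[3], th[1], th[2], 4),
                    c(1.2, 0.8, y), eps = 1e-5)
  expect_equal(g, fd, tolerance = 1e-4)
})

test_that("one-step-ahead fit profiles to the truncated-density mode
          (boundary at the last record when it exceeds the parent mode)", {
  r <- sim_records(20, 1, 1, seed = 9)
  z <- as.numeric(r)[20]
  pl1 <- predict_record_pl(r, m = 21)   # k = 1
  expect_gt(pl1$predicted, z)
  expect_true(pl1$converged)
  # the parent mode at the fitted parameters sits far below z, so the
  # truncated-density mode is the boundary and the fitted y hugs the record
  p <- pl1$coefficients
  mode <- (p[["phi"]] * p[["gamma"]] / (p[["gamma"]] + 1))^(1 / p[["gamma"]])
  expect_lt(mode, z)
  expect_true(pl1$boundary)
  expect_lt((pl1$predicted - z) / z, 1e-6)
})
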