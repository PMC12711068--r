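test_that("log-likelihood matches hand evaluation and the product form", {
  expect_equal(loglik_records(records(1), 1, 1), -1)
  expect_equal(loglik_records(records(c(1, 2)), 1, 1),
               -2 * log(2) - 1.5 - log(1 - exp(-1)))
  # exp(loglik) equals the term-wise product: f(x_n) prod f(x_i)/(1-F(x_i))
  r <- sim_records(5, 1.3, 0.9, seed = 12)
  x <- as.numeric(r)
  prod_form <- dinvweibull(x[5], 1.3, 0.9) *
    prod(dinvweibull(x[-5], 1.3, 0.9) /
           pinvweibull(x[-5], 1.3, 0.9, lower.tail = FALSE))
  expect_equal(exp(loglik_records(r, 1.3, 0.9)), prod_form,
               tolerance = 1e-10)
})

test_that("analytic score matches finite differences and has the right
          small-phi limit", {
  r <- sim_records(20, 1, 1, seed = 5)
  for (p in list(c(1, 1), c(0.6, 1.7), c(2.5, 0.5))) {
    s <- score_records(r, p[1], p[2])
    fd <- fd_gradient(function(th) loglik_records(r, th[1], th[2]), p)
    expect_equal(unname(s), fd, tolerance = 1e-5)
  }
  # n/phi dominates as phi -> 0+
  expect_gt(score_records(r, 1e-8, 1)[["phi"]], 0)
})

test_that("observed information is symmetric, matches the finite-difference
          Hessian, and is positive definite at the MLE", {
  r <- sim_records(50, 1, 1, seed = 8)
  I <- obsinfo_records(r, 1.1, 0.9)
  expect_equal(I[1, 2], I[2, 1], tolerance = 1e-10)
  # differentiate the (independently FD-validated) score: second-order
  # FD of the log-likelihood itself is too blunt for the steep gamma
  # curvature that huge record values induce
  eps <- 1e-6
  Hfd <- cbind(
    (score_records(r, 1.1 + eps, 0.9) - score_records(r, 1.1 - eps, 0.9)) / (2 * eps),
    (score_records(r, 1.1, 0.9 + eps) - score_records(r, 1.1, 0.9 - eps)) / (2 * eps))
  expect_equal(unname(I), unname(-Hfd), tolerance = 1e-5)
  # and the blunt check still holds at a coarse tolerance
  Hfd2 <- fd_hessian(function(th) loglik_records(r, th[1], th[2]), c(1.1, 0.9))
  expect_equal(unname(I), -Hfd2, tolerance = 1e-2)
  f <- iwrec(r)
  Im <- obsinfo_records(r, coef(f)[1], coef(f)[2])
  expect_true(all(eigen(Im, symmetric = TRUE)$values > 0))
})

test_that("the fitted MLE agrees with a log-grid-search oracle", {
  r <- sim_records(50, 1, 1, seed = 42)
  f <- iwrec(r)
  expect_true(f$converged)
  expect_lt(f$score_norm, 1e-6)
  oracle <- grid_mle_oracle(r)
  expect_equal(unname(coef(f)), unname(oracle), tolerance = 1e-3)
})

test_that("natural-space optimization reproduces the log-space fit", {
  r <- sim_records(30, 1, 1, seed = 14)
  f <- iwrec(r)
  nat <- optim(c(1, 1), function(p) {
    if (any(p <= 0)) return(1e10)
    -loglik_records(r, p[1], p[2])
  }, control = list(maxit = 5000, reltol = 1e-15))
  nat <- optim(nat$par, function(p) -loglik_records(r, p[1], p[2]),
               control = list(maxit = 5000, reltol = 1e-15))
  expect_equal(unname(coef(f)), nat$par, tolerance = 1e-5)
})

test_that("single-record samples are refused (unbounded likelihood)", {
  expect_error(iwrec(records(2)), "n >= 2")
})

test_that("Wald limits are symmetric with the standard normal multiplier", {
  r <- sim_records(40, 1, 1, seed = 3)
  f <- iwrec(r, level = 0.95)
  ci <- confint(f, level = 0.95)
  expect_equal(qnorm(0.975), 1.959964, tolerance = 1e-6)
  expect_equal(unname(rowMeans(ci)), unname(coef(f)), tolerance = 1e-12)
  expect_equal(unname(ci[, 2] - ci[, 1]), unname(2 * qnorm(0.975) * f$se),
               tolerance = 1e-10)
  expect_error(confint(f, level = 1.2), "level")
})

test_that("spread of the gamma estimate shrinks as more records accrue", {
  s <- sim_study_mle(n = c(10, 30, 50), reps = 200, seed = 6)
  expect_true(all(diff(s$sd_gamma) < 0))
  expect_true(all(s$failed < 0.25))
})
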