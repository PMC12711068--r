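test_that("gamma prior moments follow the closed forms", {
  expect_equal(unname(prior_moments(iw_prior(3, 3, 3, 3))),
               c(1, 1 / 3, 1, 1 / 3))
  expect_equal(unname(prior_moments(iw_prior(1, 0.6, 1, 0.6))),
               c(5 / 3, 25 / 9, 5 / 3, 25 / 9), tolerance = 1e-12)
  expect_equal(unname(prior_moments(iw_prior(1, 1, 1, 1))), c(1, 1, 1, 1))
  expect_error(iw_prior(0, 1, 1, 1), "positive")
})

test_that("log prior: hand value, gamma-density differences, mode", {
  pr <- iw_prior(1, 1, 1, 1)
  expect_equal(log_prior(2, 3, pr), -5)
  pr2 <- iw_prior(2.5, 1.3, 1.8, 0.7)
  d <- log_prior(1.4, 2.2, pr2) - log_prior(0.6, 0.9, pr2)
  ref <- dgamma(1.4, 2.5, 1.3, log = TRUE) + dgamma(2.2, 1.8, 0.7, log = TRUE) -
    dgamma(0.6, 2.5, 1.3, log = TRUE) - dgamma(0.9, 1.8, 0.7, log = TRUE)
  expect_equal(d, ref, tolerance = 1e-10)
  # maximizer over phi at fixed gamma is (e-1)/f
  opt <- optimize(function(p) log_prior(p, 1, iw_prior(3, 2, 1, 1)),
                  c(0.01, 10), maximum = TRUE)
  expect_equal(opt$maximum, (3 - 1) / 2, tolerance = 1e-4)
  expect_identical(log_prior(-1, 1, pr), -Inf)
})

test_that("log posterior = log prior + log likelihood; flat-prior limit
          recovers the MLE argmax", {
  r <- sim_records(15, 1, 1, seed = 2)
  pr <- iw_prior(2, 2, 2, 2)
  expect_equal(log_posterior(r, 1.2, 0.8, pr) - loglik_records(r, 1.2, 0.8),
               log_prior(1.2, 0.8, pr))
  expect_true(is.finite(log_posterior(r, 0.01, 5, pr)))
  flat <- iw_prior(1, 1e-8, 1, 1e-8)
  g <- exp(seq(log(0.1), log(10), length.out = 80))
  post <- outer(g, g, Vectorize(function(a, b) log_posterior(r, a, b, flat)))
  lik <- outer(g, g, Vectorize(function(a, b) loglik_records(r, a, b)))
  expect_equal(which(post == max(post)), which(lik == max(lik)))
})

test_that("with no data the sampler reproduces the prior", {
  pr <- iw_prior(3, 3, 2, 4)
  d <- mh_records(numeric(0), pr, mcmc_control(8000, seed = 9))
  s <- posterior_summary(d)
  pm <- prior_moments(pr)
  expect_lt(abs(s$estimate[1] - pm[["mean_phi"]]), 3 * s$mc_error[1])
  expect_lt(abs(s$estimate[2] - pm[["mean_gamma"]]), 3 * s$mc_error[2])
})

test_that("posterior means agree with a 2-D quadrature oracle", {
  r <- sim_records(50, 1, 1, seed = 99)
  pr <- iw_prior(3, 3, 3, 3)
  oracle <- quadrature_posterior_mean(r, pr, m = 240L)
  d <- mh_records(r, pr, mcmc_control(60000, seed = 10))
  s <- posterior_summary(d)
  expect_lt(abs(s$estimate[1] - oracle[["phi"]]), 0.02)
  expect_lt(abs(s$estimate[2] - oracle[["gamma"]]), 0.02)
})

test_that("the chain is seed-deterministic with sane acceptance", {
  r <- sim_records(25, 1, 1, seed = 4)
  d1 <- mh_records(r, iw_prior(3, 3, 3, 3), mcmc_control(4000, seed = 1))
  d2 <- mh_records(r, iw_prior(3, 3, 3, 3), mcmc_control(4000, seed = 1))
  expect_identical(d1$draws, d2$draws)
  expect_gt(d1$acceptance_rate, 0.1)
  expect_lt(d1$acceptance_rate, 0.9)
  expect_error(mcmc_control(50), "at least 100")
  expect_error(mcmc_control(1000, burn = 1000), "burn")
})

test_that("posterior summaries: degenerate and uniform-grid chains", {
  const <- matrix(2, 200, 2, dimnames = list(NULL, c("phi", "gamma")))
  s <- posterior_summary(const)
  expect_equal(s$estimate, c(2, 2))
  expect_equal(s$se, c(0, 0))
  expect_equal(s$mc_error, c(0, 0))
  expect_equal(s$median, c(2, 2))
  grid <- matrix(rep((1:1000) / 1000, 2), ncol = 2,
                 dimnames = list(NULL, c("phi", "gamma")))
  sg <- posterior_summary(grid)
  expect_lt(abs(sg$median[1] - 0.5), 1e-3)
  expect_lt(abs(sg$q2.5[1] - 0.025), 2e-3)
  expect_lt(abs(sg$q97.5[1] - 0.975), 2e-3)
  ci <- credible_interval(grid, 0.95)
  expect_lt(max(abs(unname(ci[1, ]) - c(0.025, 0.975))), 2e-3)
  expect_error(credible_interval(grid, 1.5), "level")
  expect_error(posterior_summary(grid[1:50, ]), "100")
})

test_that("mc_error never exceeds the posterior spread", {
  r <- sim_records(10, 1, 1, seed = 13)
  d <- mh_records(r, iw_prior(2, 2, 2, 2), mcmc_control(4000, seed = 2))
  s <- posterior_summary(d)
  expect_true(all(s$mc_error <= s$se))
  expect_true(all(s$q2.5 <= s$median & s$median <= s$q97.5))
})

test_that("a sharper prior at the same mean pulls the posterior towards it", {
  r <- sim_records(12, 1, 1, seed = 55)
  dist_to_one <- vapply(c(1, 10, 80), function(cc) {
    d <- mh_records(r, iw_prior(cc, cc, cc, cc), mcmc_control(8000, seed = 3))
    abs(posterior_summary(d)$estimate[1] - 1)
  }, numeric(1))
  expect_true(all(diff(dist_to_one) < 0))
})

test_that("sensitivity table has two rows per prior on shared data", {
  r <- sim_records(15, 1, 1, seed = 21)
  priors <- list(iw_prior(1, 1, 1, 1), iw_prior(2, 2, 2, 2),
                 iw_prior(3, 3, 3, 3))
  tab <- sensitivity_table(r, priors, mcmc_control(2000, seed = 5))
  expect_equal(nrow(tab), 2L * length(priors))
  expect_equal(tab$parameter, rep(c("phi", "gamma"), length(priors)))
  expect_equal(tab$shape[1:2], c(1, 1))
  expect_true(all(tab$q2.5 <= tab$median & tab$median <= tab$q97.5))
})
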