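test_that("d = 1 marginal fit recovers a one-component alternative", {
  sim <- marginal_sim(4000, weights = c(0.6, 0.4), means = 2.5,
                      extra_vars = 1.5, seed = 21)
  fit <- suppressWarnings(
    fit_marginal_gmm(sim$values, sim$variances, d = 1, seed = 21))
  expect_lt(abs(fit$weights[1] - 0.6), 0.05)
  expect_lt(abs(fit$means[2] - 2.5), 0.15)
  expect_lt(abs(fit$extra_vars[2] - 1.5), 0.5)
  expect_true(all(diff(fit$loglik_path) > -1e-8 * abs(fit$loglik)))
})

test_that("all-null data push non-null weights toward zero when d = 2", {
  set.seed(33)
  x <- rnorm(2000)
  fit <- suppressWarnings(
    fit_marginal_gmm(x, rep(1, 2000), d = 2, seed = 33))
  expect_lte(fit$weights[2], 0.06)
  expect_lte(fit$weights[3], 0.06)
})

test_that("marginal proportions recover the composite generator weights", {
  # generator weights and moments of the composite design at tau = 1.9;
  # the components overlap heavily, so estimates are averaged over seeds
  tau <- 1.9
  W <- t(sapply(1:20, function(s) {
    sim <- marginal_sim(5000, weights = c(0.54, 0.18, 0.28),
                        means = c(0.05 * tau, -0.5 * tau),
                        extra_vars = c(1, 2), seed = 40 + s)
    fit <- suppressWarnings(
      fit_marginal_gmm(sim$values, sim$variances, d = 2, tol = 1e-6,
                       max_iter = 400, seed = 40 + s, n_restarts = 2))
    # components are exchangeable in label; order non-null weights
    c(fit$weights[1], sort(fit$weights[2:3]))
  }))
  w_bar <- colMeans(W)
  expect_lt(abs(w_bar[1] - 0.54), 0.07)
  expect_lt(abs(w_bar[2] - 0.18), 0.07)
  expect_lt(abs(w_bar[3] - 0.28), 0.07)
})

test_that("AIC selects the generating component count", {
  # one well-separated non-null component
  sim1 <- marginal_sim(5000, weights = c(0.5, 0.5), means = 4,
                       extra_vars = 1, seed = 51)
  d1 <- select_components_aic(sim1$values, sim1$variances, d_max = 3,
                              seed = 51, n_restarts = 2)
  expect_identical(as.integer(d1), 1L)
  # two well-separated non-null components
  sim2 <- marginal_sim(5000, weights = c(0.4, 0.3, 0.3), means = c(-5, 5),
                       extra_vars = c(1, 1), seed = 52)
  d2 <- select_components_aic(sim2$values, sim2$variances, d_max = 3,
                              tol = 1e-6, max_iter = 400,
                              seed = 52, n_restarts = 2)
  expect_identical(as.integer(d2), 2L)
  expect_length(attr(d2, "aic"), 3)
  # a single candidate is returned unconditionally
  expect_identical(
    as.integer(select_components_aic(sim1$values, sim1$variances, d_max = 1,
                                     seed = 1, n_restarts = 1)), 1L)
})

test_that("joint proportions recover an independence truth", {
  cp <- true_composite_prior(scenario_config("composite", tau = 1.9))
  null_mass_true <- sum(cp$pi[1, ]) + sum(cp$pi[, 1]) - cp$pi[1, 1]
  est <- t(sapply(1:5, function(s) {
    sim <- generate_statistics(cp, m = 5000, var1 = 1, var2 = 1,
                               seed = 60 + s)
    marg_a <- suppressWarnings(
      fit_marginal_gmm(sim$summary$a, sim$summary$var1, d = 2, tol = 1e-6,
                       max_iter = 400, seed = 60 + s, n_restarts = 2))
    marg_b <- suppressWarnings(
      fit_marginal_gmm(sim$summary$b, sim$summary$var2, d = 2, tol = 1e-6,
                       max_iter = 400, seed = 80 + s, n_restarts = 2))
    fit <- suppressWarnings(
      fit_joint_proportions(sim$summary, marg_a, marg_b, tol = 1e-6))
    stopifnot(all(diff(fit$loglik_path) > -1e-6 * abs(fit$loglik)),
              abs(sum(fit$pi) - 1) < 1e-10)
    # truth is the product of the generator margins; component labels
    # within a margin are exchangeable, so compare label-free masses
    c(null = sum(fit$pi[1, ]) + sum(fit$pi[, 1]) - fit$pi[1, 1],
      p00 = fit$pi[1, 1])
  }))
  expect_lt(abs(mean(est[, "null"]) - null_mass_true), 0.05)
  expect_lt(abs(mean(est[, "p00"]) - cp$pi[1, 1]), 0.05)
})

test_that("pure-null data leave nearly all joint mass on the (0,0) cell", {
  set.seed(71)
  m <- 3000
  s <- coef_summary(rnorm(m), rnorm(m), rep(1, m), rep(1, m), n = 100)
  marg_a <- suppressWarnings(fit_marginal_gmm(s$a, s$var1, d = 1, seed = 71))
  marg_b <- suppressWarnings(fit_marginal_gmm(s$b, s$var2, d = 1, seed = 72))
  fit <- suppressWarnings(fit_joint_proportions(s, marg_a, marg_b))
  expect_gte(fit$pi[1, 1], 0.95)
})

test_that("composite lfdr with d1 = d2 = 1 equals the simple lfdr", {
  sim <- stat_sim(m = 400, seed = 81)
  pr <- mixture_prior(c(0.4, 0.2, 0.2, 0.2), 2, 1, -3, 4)
  cp <- structure(list(mu = c(0, 2), kappa = c(0, 1),
                       theta = c(0, -3), psi = c(0, 4),
                       pi = matrix(c(0.4, 0.2, 0.2, 0.2), 2, 2),
                       d1 = 1L, d2 = 1L),
                  class = "composite_prior")
  expect_equal(compute_lfdr(sim$summary, cp),
               compute_lfdr(sim$summary, pr), tolerance = 1e-12)
})
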