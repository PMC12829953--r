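test_that("lfdr at the origin matches a hand density-ratio computation", {
  # equal proportions, means 3 on both axes, no extra variance, sigma = 1
  pr <- mixture_prior(c(0.25, 0.25, 0.25, 0.25), mu = 3, psi = 0,
                      theta = 3, kappa = 0)
  s <- coef_summary(a = 0, b = 0, var1 = 1, var2 = 1, n = 100)
  phi0 <- dnorm(0); phi3 <- dnorm(-3)
  num <- phi0 * phi0 + phi3 * phi0 + phi0 * phi3
  den <- num + phi3 * phi3
  expect_equal(compute_lfdr(s, pr), num / den, tolerance = 1e-12)
})

test_that("degenerate priors give lfdr near the corners", {
  # evaluated on data drawn from the matching prior
  sim_alt <- stat_sim(m = 100, pi = c(1e-9, 1e-9, 1e-9, 1 - 3e-9), seed = 4)
  all_alt <- mixture_prior(c(1e-9, 1e-9, 1e-9, 1 - 3e-9), 2, 1, -3, 4)
  expect_lt(max(compute_lfdr(sim_alt$summary, all_alt)), 0.01)
  sim_null <- stat_sim(m = 100, pi = c(1 - 3e-9, 1e-9, 1e-9, 1e-9), seed = 4)
  all_null <- mixture_prior(c(1 - 3e-9, 1e-9, 1e-9, 1e-9), 2, 1, -3, 4)
  expect_gt(min(compute_lfdr(sim_null$summary, all_null)), 0.99)
})

test_that("step_up reproduces the worked running-mean example", {
  res <- step_up(c(0.01, 0.02, 0.10, 0.30), alpha = 0.05)
  expect_equal(res$running_mean, c(0.01, 0.015, cumsum(c(0.01, 0.02, 0.1))[3] / 3,
                                   0.1075))
  expect_identical(res$k_reject, 3L)
  expect_equal(res$delta_hat, 0.10)
  expect_equal(res$rejected, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("step_up boundary cases behave as specified", {
  expect_identical(step_up(rep(0, 7), 0.05)$k_reject, 7L)
  res <- step_up(c(0.2, 0.6, 0.9), 0.1)
  expect_identical(res$k_reject, 0L)
  expect_equal(res$delta_hat, 0)
  expect_false(any(res$rejected))
  expect_error(step_up(c(-0.1, 0.5), 0.05), "\\[0, 1\\]")
  expect_error(step_up(c(0.1, 1.5), 0.05), "\\[0, 1\\]")
})

test_that("step_up agrees with the sup-form threshold on random vectors", {
  set.seed(77)
  for (rep in 1:200) {
    m <- sample(1:100, 1)
    lf <- runif(m)
    alpha <- runif(1, 0.01, 0.4)
    su <- step_up(lf, alpha)
    delta <- threshold_sup_form(lf, alpha)
    rej_sup <- if (is.na(delta)) rep(FALSE, m) else lf <= delta
    expect_identical(su$rejected, rej_sup)
  }
})

test_that("the full-set average is Q at the largest threshold", {
  lf <- runif(50)
  expect_equal({
    t_max <- max(lf)
    sum(lf[lf <= t_max]) / sum(lf <= t_max)
  }, mean(lf))
  # and the sup-form threshold rejects everything when mean(lf) <= alpha
  lf_small <- runif(50, 0, 0.02)
  expect_equal(threshold_sup_form(lf_small, alpha = 0.5), max(lf_small))
})

test_that("rejections are monotone non-decreasing in alpha", {
  sim <- stat_sim(m = 1500, seed = 6)
  pr <- mixture_prior(c(0.4, 0.2, 0.2, 0.2), 2, 1, -3, 4)
  lf <- compute_lfdr(sim$summary, pr)
  ks <- sapply(c(0.01, 0.05, 0.1, 0.2, 0.3), function(al)
    step_up(lf, al)$k_reject)
  expect_true(all(diff(ks) >= 0))
})

test_that("oracle diagnostics satisfy the counting identities", {
  sim <- stat_sim(m = 800, seed = 10)
  pr <- mixture_prior(c(0.4, 0.2, 0.2, 0.2), 2, 1, -3, 4)
  lf <- compute_lfdr(sim$summary, pr)
  d <- oracle_diagnostics(lf, sim$truth, grid = c(0.05, 0.2, 0.5, 1))
  expect_true(all(d$Vm <= d$Rm))
  expect_true(all(d$Wm <= d$Rm))
  # partition: false + true rejections = all rejections
  true_rej <- sapply(d$delta, function(t) sum(lf <= t & sim$truth$is_alt))
  expect_equal(d$Vm + true_rej, d$Rm)
  # at delta >= max(lfdr) everything is rejected and nothing is missed
  expect_equal(d$Rm[d$delta == 1], 800)
  expect_equal(d$Pm[d$delta == 1], 0)
  # G_jk are monotone in t
  for (cn in c("G00", "G10", "G01", "G11"))
    expect_true(all(diff(d[[cn]]) >= 0))
})

test_that("Wm/Rm estimates the oracle false-rejection fraction on average", {
  # with the true prior, E[Wm] and E[Vm] agree at a fixed threshold
  pr <- mixture_prior(c(0.4, 0.2, 0.2, 0.2), 2, 1, -3, 4)
  delta <- 0.3
  stats <- t(sapply(1:200, function(s) {
    sim <- stat_sim(m = 400, seed = 2000 + s)
    lf <- compute_lfdr(sim$summary, pr)
    sel <- lf <= delta
    c(V = sum(sel & !sim$truth$is_alt), W = sum(lf[sel]))
  }))
  diff_mean <- mean(stats[, "V"] - stats[, "W"])
  diff_se <- sd(stats[, "V"] - stats[, "W"]) / sqrt(nrow(stats))
  expect_lt(abs(diff_mean), 2 * diff_se + 1e-9)
})

test_that("screen_table carries ranks and rejection flags consistently", {
  sim <- stat_sim(m = 200, seed = 12)
  res <- mlfdr_screen(sim$summary, alpha = 0.1,
                      prior = mixture_prior(c(0.4, 0.2, 0.2, 0.2), 2, 1, -3, 4))
  tab <- screen_table(res, sim$summary)
  expect_equal(sort(tab$rank), 1:200)
  expect_equal(sum(tab$rejected), res$k_reject)
  expect_true(all(tab$lfdr[tab$rejected] <= res$delta_hat + 1e-12))
})
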