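test_that("generation is deterministic in the seed and varies across seeds", {
  cfg <- scenario_config("linear", n = 50, m = 30, tau = 1, seed = 5)
  s1 <- generate_scenario(cfg)
  s2 <- generate_scenario(cfg)
  expect_identical(s1$data$mediators, s2$data$mediators)
  expect_identical(s1$truth$xi, s2$truth$xi)
  s3 <- generate_scenario(scenario_config("linear", n = 50, m = 30, tau = 1,
                                          seed = 6))
  expect_false(identical(s1$truth$xi, s3$truth$xi))
})

test_that("latent-state frequencies match the dense proportions", {
  sim <- generate_scenario(scenario_config("linear", "dense", n = 30,
                                           m = 100000, tau = 1, seed = 2))
  xi <- sim$truth$xi
  frac00 <- mean(xi[, 1] == 0 & xi[, 2] == 0)
  expect_equal(frac00, 0.4, tolerance = 0.01)
  expect_equal(mean(xi[, 1] == 1 & xi[, 2] == 1), 0.2, tolerance = 0.01)
})

test_that("tau = 0 leaves only the coefficient noise terms", {
  sim <- generate_scenario(scenario_config("linear", n = 100, m = 50000,
                                           tau = 0, seed = 3))
  alt_a <- sim$truth$alpha_true[sim$truth$xi[, 1] == 1]
  expect_equal(mean(alt_a), 0, tolerance = 3 * sqrt(1 / 100) / sqrt(length(alt_a)) * 3)
  # mean |alpha| over non-null units ~ E|N(0, 1/n)|
  expect_equal(mean(abs(alt_a)), sqrt(2 / (pi * 100)), tolerance = 0.005)
})

test_that("coefficient invariants hold across scenarios", {
  for (sc in c("linear", "confounder", "binary", "interaction",
               "latent_pleiotropy", "composite")) {
    sim <- generate_scenario(scenario_config(sc, n = 60, m = 40, tau = 1,
                                             seed = 8))
    expect_true(all((sim$truth$alpha_true == 0) == (sim$truth$xi[, 1] == 0)),
                label = sc)
    expect_true(all((sim$truth$beta_true == 0) == (sim$truth$xi[, 2] == 0)),
                label = sc)
    expect_identical(sim$data$outcome_type,
                     if (sc == "binary") "binary" else "continuous")
  }
})

test_that("null-standardized statistics are approximately standard normal", {
  sim <- generate_scenario(scenario_config("linear", "dense", n = 200,
                                           m = 5000, tau = 1.3, seed = 14))
  s <- fit_structural_models(sim$data)
  null_a <- sim$truth$xi[, 1] == 0
  z <- s$a[null_a] / sqrt(s$var1[null_a])
  expect_gt(ks.test(z, "pnorm")$p.value, 0.01)
  null_b <- sim$truth$xi[, 2] == 0
  zb <- s$b[null_b] / sqrt(s$var2[null_b])
  expect_gt(ks.test(zb, "pnorm")$p.value, 0.01)
})

test_that("evaluate_rejections matches exhaustive counting", {
  set.seed(17)
  truth <- structure(list(xi = cbind(rbinom(60, 1, 0.5), rbinom(60, 1, 0.5))),
                     class = "sim_truth")
  truth$is_alt <- truth$xi[, 1] > 0 & truth$xi[, 2] > 0
  rej <- as.logical(rbinom(60, 1, 0.3))
  ev <- evaluate_rejections(rej, truth)
  # brute-force counts
  V <- 0; TP <- 0
  for (i in 1:60) {
    if (rej[i] && !(truth$xi[i, 1] == 1 && truth$xi[i, 2] == 1)) V <- V + 1
    if (rej[i] && truth$xi[i, 1] == 1 && truth$xi[i, 2] == 1) TP <- TP + 1
  }
  expect_equal(ev$fdp, V / max(sum(rej), 1))
  expect_equal(ev$power, TP / sum(truth$is_alt))
  # conventions
  expect_equal(evaluate_rejections(rep(FALSE, 60), truth)$fdp, 0)
  expect_equal(evaluate_rejections(truth$is_alt, truth)$power, 1)
  expect_equal(evaluate_rejections(truth$is_alt, truth)$fdp, 0)
})

test_that("run_grid returns a reproducible tidy table", {
  g1 <- run_grid("linear", taus = 0.9, n_values = 100, reps = 2,
                 alpha = 0.1, m = 60, method = "oracle", seed = 23)
  g2 <- run_grid("linear", taus = 0.9, n_values = 100, reps = 2,
                 alpha = 0.1, m = 60, method = "oracle", seed = 23)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 2)
  expect_named(g1, c("method", "fdp", "power", "n_reject", "scenario",
                     "tau", "n", "replicate"))
})

test_that("baseline hooks are scored alongside the main method", {
  reject_none <- function(summary, alpha) rep(FALSE, nrow(summary))
  g <- run_grid("linear", taus = 0.9, n_values = 100, reps = 2, alpha = 0.1,
                m = 60, method = "oracle", seed = 29,
                baselines = list(nullrule = reject_none))
  expect_setequal(unique(g$method), c("mlfdr", "nullrule"))
  expect_true(all(g$n_reject[g$method == "nullrule"] == 0))
})

test_that("statistic-level generator matches its prior in law", {
  pr <- mixture_prior(c(0.4, 0.2, 0.2, 0.2), 2, 1, -3, 4)
  sim <- generate_statistics(pr, m = 50000, seed = 31)
  expect_equal(mean(sim$truth$xi[, 1] == 0), 0.6, tolerance = 0.01)
  alt_a <- sim$summary$a[sim$truth$xi[, 1] == 1]
  expect_equal(mean(alt_a), 2, tolerance = 0.05)
  expect_equal(var(alt_a), 2, tolerance = 0.1)   # sigma^2 + psi
})

test_that("composite scenario runs end-to-end with the two-step model", {
  g <- run_grid("composite", taus = 1.9, n_values = 200, reps = 1,
                alpha = 0.1, m = 400, method = "adaptive", seed = 37,
                n_restarts = 1, em_tol = 1e-6)
  expect_equal(nrow(g), 1)
  expect_true(g$fdp >= 0 && g$fdp <= 1)
  g_o <- run_grid("composite", taus = 1.9, n_values = 200, reps = 1,
                  alpha = 0.1, m = 400, method = "oracle", seed = 37)
  expect_true(is.finite(g_o$power))
})
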