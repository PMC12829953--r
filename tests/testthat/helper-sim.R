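# Shared fixtures, built in code at test time.

# Small linear-model dataset with known latent states.
tiny_linear_sim <- function(n = 120, m = 40, tau = 1.5, seed = 7,
                            sparsity = "dense") {
  generate_scenario(scenario_config("linear", sparsity, n = n, m = m,
                                    tau = tau, seed = seed))
}

# Statistic-level draw from the standard four-component model with unit
# sampling variances; strong, well-separated components unless overridden.
stat_sim <- function(m = 2000, pi = c(0.4, 0.2, 0.2, 0.2), mu = 2,
                     psi = 1, theta = -3, kappa = 4, seed = 1) {
  generate_statistics(mixture_prior(pi, mu, psi, theta, kappa),
                      m = m, var1 = 1, var2 = 1, seed = seed)
}

# Univariate draw from a null-pinned marginal mixture (weights include the
# null component first); returns values and the component labels.
marginal_sim <- function(m, weights, means, extra_vars, var = 1, seed = 1) {
  stopifnot(length(weights) == length(means) + 1L)
  set.seed(seed)
  comp <- sample.int(length(weights), m, replace = TRUE, prob = weights)
  mu <- c(0, means)[comp]
  v <- var + c(0, extra_vars)[comp]
  list(values = rnorm(m, mu, sqrt(v)), comp = comp - 1L,
       variances = rep(var, m))
}
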