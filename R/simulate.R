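#' Configure a simulation scenario
#'
#' Collects the knobs of the synthetic study designs used to evaluate the
#' screening procedure: the data-generating scenario, the sparsity of the
#' latent states, sample size, number of units, and the mediation signal
#' strength `tau`.
#'
#' Scenarios:
#' * `linear` — mediator and outcome both linear with Bernoulli(0.1)
#'   exposure, unit error variance.
#' * `confounder` — adds a measured standard-normal confounder with
#'   U(0, 0.5) effects on both equations.
#' * `binary` — logistic outcome model (logit intercept 0).
#' * `interaction` — outcome contains unknown exposure-mediator
#'   interactions over a hidden set of 20 mediators.
#' * `latent_pleiotropy` — two unmeasured confounders (loadings 0.4, 0.5 on
#'   the mediators; -0.5 on the outcome) plus dense pleiotropy from a
#'   hidden set of 20 mediators.
#' * `composite` — non-null coefficients drawn from two-component Gaussian
#'   mixtures on each axis (composite alternative).
#'
#' Under the dense design the latent-state proportions
#' \eqn{(\pi_{00}, \pi_{10}, \pi_{01}, \pi_{11})} are (0.4, 0.2, 0.2, 0.2);
#' under the sparse design (0.88, 0.05, 0.05, 0.02). Non-null coefficients
#' are \eqn{\alpha_i = 0.05\tau + h_i}, \eqn{h_i \sim N(0, 1/n)} and
#' \eqn{\beta_i = -0.5\tau + g_i}, \eqn{g_i \sim N(0, 4/n)}.
#'
#' @param scenario One of `"linear"`, `"confounder"`, `"binary"`,
#'   `"interaction"`, `"latent_pleiotropy"`, `"composite"`.
#' @param sparsity `"dense"` or `"sparse"`.
#' @param n Sample size.
#' @param m Number of units.
#' @param tau Mediation signal strength (>= 0).
#' @param seed Integer seed; all randomness in [generate_scenario()] flows
#'   from it.
#' @param s_size Size of the hidden mediator set for the interaction and
#'   pleiotropy scenarios.
#' @param interaction_range,pleiotropy_range Ranges of the uniform draws
#'   for the hidden interaction / pleiotropy coefficients.
#' @param error_sd Error standard deviation of both structural equations.
#' @param composite_weights_a,composite_weights_b Length-3 mixture weights
#'   (null first) for the composite scenario.
#' @param pi Optional length-4 override of the latent-state proportions
#'   (order 00, 10, 01, 11), e.g. `c(1, 0, 0, 0)` for a global-null design;
#'   when supplied it replaces the `sparsity` presets.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("linear", "confounder", "binary",
                                         "interaction", "latent_pleiotropy",
                                         "composite"),
                            sparsity = c("dense", "sparse"),
                            n = 300L, m = 1000L, tau = 1, seed = 1L,
                            s_size = 20L,
                            interaction_range = c(0.3, 0.6),
                            pleiotropy_range = c(0.3, 0.6),
                            error_sd = 1,
                            composite_weights_a = c(0.54, 0.18, 0.28),
                            composite_weights_b = c(0.6, 0.05, 0.35),
                            pi = NULL) {
  scenario <- match.arg(scenario)
  sparsity <- match.arg(sparsity)
  stopifnot(tau >= 0, n > 0, m > 0)
  if (is.null(pi)) {
    pi <- if (sparsity == "dense") c(0.4, 0.2, 0.2, 0.2)
          else c(0.88, 0.05, 0.05, 0.02)
  } else {
    stopifnot(length(pi) == 4, all(pi >= 0), abs(sum(pi) - 1) < 1e-8)
  }
  structure(list(scenario = scenario, sparsity = sparsity, pi = pi,
                 n = as.integer(n), m = as.integer(m), tau = tau,
                 seed = as.integer(seed), s_size = as.integer(s_size),
                 interaction_range = interaction_range,
                 pleiotropy_range = pleiotropy_range, error_sd = error_sd,
                 composite_weights_a = composite_weights_a,
                 composite_weights_b = composite_weights_b),
            class = "scenario_config")
}

#' Generate a synthetic mediation dataset with known truth
#'
#' Draws latent states, coefficients and data matrices according to the
#' scenario in `config`. All randomness comes from `config$seed`; repeated
#' calls are bit-identical.
#'
#' @param config A [scenario_config()].
#' @return List with elements `data` (a [mediation_dataset()]) and `truth`
#'   (a `sim_truth`: `xi` m x 2 latent states, `alpha_true`, `beta_true`,
#'   `is_alt`, plus scenario internals such as the hidden set `S`).
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$seed, generate_scenario_impl(config))
}

generate_scenario_impl <- function(cf) {
  n <- cf$n; m <- cf$m; tau <- cf$tau
  X <- stats::rbinom(n, 1, 0.1)
  # guard against the measure-zero all-constant exposure draw
  while (stats::var(X) == 0) X <- stats::rbinom(n, 1, 0.1)

  if (cf$scenario == "composite") {
    xi1 <- sample(0:2, m, replace = TRUE, prob = cf$composite_weights_a)
    xi2 <- sample(0:2, m, replace = TRUE, prob = cf$composite_weights_b)
    mu_comp <- c(0, 0.05 * tau, -0.5 * tau)
    kap_comp <- c(0, 1, 2)
    th_comp <- c(0, 0.9 * tau, -0.01 * tau)
    psi_comp <- c(0, 1.5, 2)
    alpha <- ifelse(xi1 > 0,
                    stats::rnorm(m, mu_comp[xi1 + 1], sqrt(kap_comp[xi1 + 1])) / sqrt(n),
                    0)
    beta <- ifelse(xi2 > 0,
                   stats::rnorm(m, th_comp[xi2 + 1], sqrt(psi_comp[xi2 + 1])) / sqrt(n),
                   0)
  } else {
    state <- sample(1:4, m, replace = TRUE, prob = cf$pi)  # 00, 10, 01, 11
    xi1 <- as.integer(state %in% c(2L, 4L))
    xi2 <- as.integer(state %in% c(3L, 4L))
    alpha <- ifelse(xi1 == 1, 0.05 * tau + stats::rnorm(m, 0, sqrt(1 / n)), 0)
    beta <- ifelse(xi2 == 1, -0.5 * tau + stats::rnorm(m, 0, sqrt(4 / n)), 0)
  }
  gamma <- stats::rnorm(m, 1, sqrt(0.5))

  E <- matrix(stats::rnorm(n * m, 0, cf$error_sd), n, m)
  Eps <- matrix(stats::rnorm(n * m, 0, cf$error_sd), n, m)
  S <- NULL; Zcov <- NULL
  outcome_type <- "continuous"

  if (cf$scenario %in% c("linear", "composite")) {
    M <- outer(X, alpha) + E
    Y <- sweep(M, 2, beta, `*`) + outer(X, gamma) + Eps
  } else if (cf$scenario == "confounder") {
    Zcov <- stats::rnorm(n)
    theta <- stats::runif(m, 0, 0.5)
    delta <- stats::runif(m, 0, 0.5)
    M <- outer(X, alpha) + outer(Zcov, theta) + E
    Y <- sweep(M, 2, beta, `*`) + outer(X, gamma) + outer(Zcov, delta) + Eps
  } else if (cf$scenario == "binary") {
    outcome_type <- "binary"
    M <- outer(X, alpha) + E
    eta <- sweep(M, 2, beta, `*`) + outer(X, gamma)
    Y <- matrix(stats::rbinom(n * m, 1, stats::plogis(eta)), n, m)
  } else if (cf$scenario == "interaction") {
    Zcov <- stats::rnorm(n)
    delta <- stats::runif(m, 0, 0.5)
    zeta <- stats::runif(m, 0, 0.5)
    M <- outer(X, alpha) + outer(Zcov, delta) + E
    S <- sample.int(m, cf$s_size)
    theta_S <- stats::runif(cf$s_size, cf$interaction_range[1],
                            cf$interaction_range[2])
    hidden <- X * drop(M[, S, drop = FALSE] %*% theta_S)
    Y <- sweep(M, 2, beta, `*`) + outer(X, gamma) + outer(Zcov, zeta) + hidden + Eps
  } else if (cf$scenario == "latent_pleiotropy") {
    Zcov <- stats::rnorm(n)
    Z1 <- stats::rnorm(n); Z2 <- stats::rnorm(n)
    theta <- stats::runif(m, 0, 0.5)
    delta <- stats::runif(m, 0, 0.5)
    M <- outer(X, alpha) + outer(Zcov, theta) + outer(Z1, rep(0.4, m)) +
      outer(Z2, rep(0.5, m)) + E
    S <- sample.int(m, cf$s_size)
    kappa_S <- stats::runif(cf$s_size, cf$pleiotropy_range[1],
                            cf$pleiotropy_range[2])
    pleio <- drop(M[, S, drop = FALSE] %*% kappa_S)
    Y <- sweep(M, 2, beta, `*`) + outer(X, gamma) + outer(Zcov, delta) -
      0.5 * Z1 + pleio + Eps
  }

  data <- mediation_dataset(X, M, Y,
                            covariates = if (is.null(Zcov)) NULL
                                         else matrix(Zcov, ncol = 1,
                                                     dimnames = list(NULL, "Z")),
                            outcome_type = outcome_type)
  truth <- structure(
    list(xi = cbind(xi1 = xi1, xi2 = xi2),
         alpha_true = alpha, beta_true = beta,
         is_alt = xi1 > 0 & xi2 > 0, S = S),
    class = "sim_truth")
  list(data = data, truth = truth)
}

#' Oracle mixture prior implied by a scenario configuration
#'
#' The true four-component prior on the root-n scale under the standard
#' (non-composite) scenarios: non-null \eqn{\sqrt{n}\,\alpha_i} has mean
#' \eqn{0.05\tau\sqrt{n}} and variance 1, non-null \eqn{\sqrt{n}\,\beta_i}
#' has mean \eqn{-0.5\tau\sqrt{n}} and variance 4, with the configured
#' state proportions. Supplying it to [compute_lfdr()] gives the oracle
#' procedure.
#'
#' @param config A [scenario_config()] (non-composite scenario).
#' @return A `mixture_prior`.
#' @export
true_prior <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$scenario == "composite")
    stop("use true_composite_prior() for the composite scenario", call. = FALSE)
  structure(list(pi = matrix(config$pi, 2, 2),
                 mu = 0.05 * config$tau * sqrt(config$n), psi = 1,
                 theta = -0.5 * config$tau * sqrt(config$n), kappa = 4,
                 loglik = NA_real_, loglik_path = numeric(0),
                 converged = TRUE),
            class = "mixture_prior")
}

#' Oracle composite prior for the composite scenario
#'
#' @param config A [scenario_config()] with `scenario = "composite"`.
#' @return A `composite_prior` with the generating moments and the
#'   independence joint-proportion table.
#' @export
true_composite_prior <- function(config) {
  stopifnot(inherits(config, "scenario_config"),
            config$scenario == "composite")
  tau <- config$tau
  structure(list(mu = c(0, 0.05 * tau, -0.5 * tau), kappa = c(0, 1, 2),
                 theta = c(0, 0.9 * tau, -0.01 * tau), psi = c(0, 1.5, 2),
                 pi = outer(config$composite_weights_a,
                            config$composite_weights_b),
                 d1 = 2L, d2 = 2L,
                 marginal_weights_a = config$composite_weights_a,
                 marginal_weights_b = config$composite_weights_b,
                 loglik = NA_real_, loglik_path = numeric(0),
                 converged = TRUE),
            class = "composite_prior")
}

#' Score a rejection set against the simulation truth
#'
#' @param result An `lfdr_screen_result`, or a logical rejection vector.
#' @param truth A `sim_truth`.
#' @return Data.frame with `fdp` (false discovery proportion; 0 when
#'   nothing is rejected), `power` (fraction of true mediation signals
#'   rejected) and `n_reject`.
#' @export
evaluate_rejections <- function(result, truth) {
  rejected <- if (is.logical(result)) result else result$rejected
  stopifnot(length(rejected) == length(truth$is_alt))
  n_reject <- sum(rejected)
  fdp <- if (n_reject > 0) sum(rejected & !truth$is_alt) / n_reject else 0
  n_alt <- sum(truth$is_alt)
  power <- if (n_alt > 0) sum(rejected & truth$is_alt) / n_alt else 0
  data.frame(fdp = fdp, power = power, n_reject = n_reject)
}

#' Run a grid of simulation cells
#'
#' For every combination of scenario, signal strength and sample size,
#' generates `reps` replicate datasets, runs the full pipeline (per-unit
#' regressions, optional latent-factor adjustment, prior estimation or the
#' oracle prior, step-up screening) and records FDP and power per
#' replicate. One root seed spawns independent per-replicate substreams.
#'
#' @param scenarios Character vector of scenario names.
#' @param taus Numeric vector of signal strengths.
#' @param n_values Integer vector of sample sizes.
#' @param reps Replicates per cell.
#' @param alpha Nominal FDR level.
#' @param sparsity `"dense"` or `"sparse"`.
#' @param m Number of units.
#' @param method `"adaptive"` (EM-estimated prior) or `"oracle"` (true
#'   generating prior).
#' @param adjust Apply the latent-factor adjustment before screening.
#' @param seed Root seed.
#' @param ... EM controls forwarded to [mlfdr_screen()] (e.g. `n_restarts`,
#'   `em_tol`, `em_max_iter`).
#' @param baselines Optional named list of baseline methods; each element
#'   is either a function `(summary, alpha) -> logical vector` or a shell
#'   command template containing `{summary}`, `{alpha}` and `{out}`
#'   placeholders. The command must write a TSV with a logical/0-1 column
#'   `rejected`. Baselines are scored on the same replicates.
#' @return Data.frame with one row per (cell, replicate, method).
#' @export
run_grid <- function(scenarios, taus, n_values, reps = 100L, alpha = 0.05,
                     sparsity = "dense", m = 1000L,
                     method = c("adaptive", "oracle"), adjust = FALSE,
                     seed = 1L, baselines = NULL, ...) {
  method <- match.arg(method)
  sub_seeds <- with_seed(seed, sample.int(2^31 - 2, reps))
  rows <- list()
  for (sc in scenarios) for (tau in taus) for (n in n_values) {
    for (r in seq_len(reps)) {
      cfg <- scenario_config(scenario = sc, sparsity = sparsity, n = n,
                             m = m, tau = tau, seed = sub_seeds[r])
      row <- tryCatch(
        run_one_replicate(cfg, alpha, method, adjust, baselines, ...),
        error = function(e) {
          warning("replicate failed (", sc, ", tau=", tau, ", n=", n,
                  ", rep=", r, "): ", conditionMessage(e))
          NULL
        })
      if (is.null(row)) next
      row$scenario <- sc; row$tau <- tau; row$n <- n; row$replicate <- r
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

run_one_replicate <- function(cfg, alpha, method, adjust, baselines, ...) {
  sim <- generate_scenario(cfg)
  summ <- if (adjust) {
    latent_adjusted_summary(sim$data, seed = cfg$seed)
  } else {
    fit_structural_models(sim$data)
  }
  prior <- if (method == "oracle") {
    if (cfg$scenario == "composite") true_composite_prior(cfg)
    else true_prior(cfg)
  } else NULL
  model <- if (cfg$scenario == "composite") "composite" else "simple"
  res <- mlfdr_screen(summ, alpha = alpha, prior = prior, model = model,
                      d1 = 2L, d2 = 2L,
                      seed = cfg$seed %% 100000L + 1L, ...)
  out <- cbind(method = "mlfdr", evaluate_rejections(res, sim$truth))
  for (nm in names(baselines)) {
    rej <- run_baseline(baselines[[nm]], summ, alpha)
    out <- rbind(out, cbind(method = nm,
                            evaluate_rejections(rej, sim$truth)))
  }
  out
}

# Baseline hook: an R function, or a shell command template writing a
# `rejected` column.
run_baseline <- function(baseline, summary, alpha) {
  if (is.function(baseline)) return(as.logical(baseline(summary, alpha)))
  stopifnot(is.character(baseline))
  tmp_in <- tempfile(fileext = ".tsv")
  tmp_out <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(tmp_in, tmp_out)))
  write_summary(summary, tmp_in)
  cmd <- gsub("{summary}", tmp_in, baseline, fixed = TRUE)
  cmd <- gsub("{alpha}", format(alpha), cmd, fixed = TRUE)
  cmd <- gsub("{out}", tmp_out, cmd, fixed = TRUE)
  status <- system(cmd)
  if (status != 0) stop("baseline command failed: ", cmd, call. = FALSE)
  tab <- utils::read.table(tmp_out, header = TRUE, sep = "\t")
  as.logical(tab$rejected)
}

#' Draw scaled statistics directly from the mixture model
#'
#' Generates \eqn{(a_i, b_i)} at the statistic level — latent states from
#' the proportion table, then independent normals with the component means
#' and variances — bypassing the raw-data structural equations. This is
#' the natural device for studying the mixture estimator itself: the
#' generating parameters are exactly the quantities the EM estimates.
#'
#' @param prior A `mixture_prior` or `composite_prior` holding the
#'   generating parameters.
#' @param m Number of units.
#' @param var1,var2 Sampling variances \eqn{\sigma_{i1}^2, \sigma_{i2}^2};
#'   scalars are recycled.
#' @param n Nominal sample size stored in the summary (the statistics are
#'   already on the root-n scale).
#' @param seed Integer seed.
#' @return List with `summary` (a [coef_summary()]) and `truth` (a
#'   `sim_truth`; for composite priors `xi` holds the component indices).
#' @export
generate_statistics <- function(prior, m, var1 = 1, var2 = 1, n = 100L,
                                seed = 1L) {
  g <- prior_grid(prior)
  var1 <- rep_len(var1, m); var2 <- rep_len(var2, m)
  with_seed(seed, {
    K <- length(g$pi)
    d1p <- nrow(g$pi)
    comp <- sample.int(K, m, replace = TRUE, prob = as.numeric(g$pi))
    u <- (comp - 1L) %% d1p + 1L
    v <- (comp - 1L) %/% d1p + 1L
    a <- stats::rnorm(m, g$a_mean[u], sqrt(var1 + g$a_var[u]))
    b <- stats::rnorm(m, g$b_mean[v], sqrt(var2 + g$b_var[v]))
    truth <- structure(
      list(xi = cbind(xi1 = u - 1L, xi2 = v - 1L),
           alpha_true = ifelse(u > 1L, g$a_mean[u], 0),
           beta_true = ifelse(v > 1L, g$b_mean[v], 0),
           is_alt = u > 1L & v > 1L, S = NULL),
      class = "sim_truth")
    list(summary = coef_summary(a, b, var1, var2, n = n), truth = truth)
  })
}

#' Convenience constructor for a simple mixture prior
#'
#' @param pi Length-4 proportions in component order 00, 10, 01, 11.
#' @param mu,psi Mean and variance of the non-null scaled alpha component.
#' @param theta,kappa Mean and variance of the non-null scaled beta
#'   component.
#' @return A `mixture_prior`.
#' @export
mixture_prior <- function(pi, mu, psi, theta, kappa) {
  stopifnot(length(pi) == 4, abs(sum(pi) - 1) < 1e-8, psi >= 0, kappa >= 0)
  structure(list(pi = matrix(pi, 2, 2), mu = mu, psi = psi, theta = theta,
                 kappa = kappa, loglik = NA_real_, loglik_path = numeric(0),
                 converged = TRUE),
            class = "mixture_prior")
}
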