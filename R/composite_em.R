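#' Fit a null-pinned univariate Gaussian mixture to one margin
#'
#' Fits, by EM, the marginal model for one axis of scaled estimates:
#' \deqn{x_i \sim \pi_0 N(0, s_i) + \sum_{u=1}^{d} \pi_u N(m_u, s_i + v_u),}
#' where component 0 is the null (mean 0, no extra variance) and the
#' unit-specific sampling variances \eqn{s_i} are known. Used as step one of
#' the two-step composite-alternative estimator.
#'
#' @param values Numeric vector of scaled estimates (one margin).
#' @param variances Positive sampling variances, same length.
#' @param d Number of non-null components (`d >= 1`).
#' @param tol,max_iter,n_restarts,seed EM controls as in [em_fit()].
#' @return List with `weights` (length `d+1`, null first), `means`,
#'   `extra_vars` (length `d+1` with the null pinned at 0), `loglik`,
#'   `loglik_path`, `converged`, `responsibilities`.
#' @export
fit_marginal_gmm <- function(values, variances, d, tol = 1e-8,
                             max_iter = 1000L, n_restarts = 3L, seed = 1L) {
  m <- length(values)
  stopifnot(d >= 1L, length(variances) == m, all(variances > 0))
  if (m < 10L * d)
    stop("need at least 10*d units for a d-component fit", call. = FALSE)

  starts <- marginal_starts(values, variances, d, n_restarts, seed)
  best <- NULL
  for (st in starts) {
    fit <- marginal_em_run(values, variances, st, tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!best$converged)
    warning("marginal EM did not converge within max_iter")
  best
}

marginal_starts <- function(x, s, d, n_restarts, seed) {
  with_seed(seed, {
    km <- tryCatch(stats::kmeans(x, centers = d, nstart = 3),
                   error = function(e) NULL)
    mu0 <- if (!is.null(km)) sort(as.numeric(km$centers))
           else stats::quantile(x, probs = seq_len(d) / (d + 1), names = FALSE)
    v0 <- rep(max(stats::var(x) - mean(s), 0.1), d)
    base <- list(weights = c(0.6, rep(0.4 / d, d)), means = mu0,
                 extra_vars = v0)
    starts <- list(base)
    if (n_restarts > 1L) {
      starts <- c(starts, lapply(seq_len(n_restarts - 1L), function(r) {
        w <- base$weights * stats::runif(d + 1, 0.5, 1.5)
        list(weights = w / sum(w),
             means = base$means * stats::runif(d, 0.5, 1.5) +
               stats::rnorm(d, 0, 0.2),
             extra_vars = base$extra_vars * stats::runif(d, 0.5, 2))
      }))
    }
    starts
  })
}

marginal_em_run <- function(x, s, st, tol, max_iter) {
  m <- length(x)
  d <- length(st$means)
  w <- st$weights; mu <- st$means; ev <- st$extra_vars
  floor_pi <- 1e-6
  path <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    L <- matrix(0, m, d + 1L)
    L[, 1] <- log(w[1]) + stats::dnorm(x, 0, sqrt(s), log = TRUE)
    for (u in seq_len(d))
      L[, u + 1L] <- log(w[u + 1L]) +
        stats::dnorm(x, mu[u], sqrt(s + ev[u]), log = TRUE)
    mx <- apply(L, 1, max)
    R <- exp(L - mx)
    rs <- rowSums(R)
    ll <- sum(mx + log(rs))
    path <- c(path, ll)
    R <- R / rs

    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-10)) {
      converged <- TRUE
      break
    }
    ll_old <- ll

    w <- pmax(colMeans(R), floor_pi)
    w <- w / sum(w)
    for (u in seq_len(d)) {
      up <- update_mean_var(x, s, R[, u + 1L], mu[u], ev[u])
      mu[u] <- up$mean; ev[u] <- up$extra_var
    }
  }

  # Near the null the likelihood is almost flat in how mass splits between
  # the null and an alternative component sitting on top of it, so the EM
  # can park arbitrary null mass there. Greedily fold back any non-null
  # component that does not earn its three parameters (mean, extra
  # variance, weight) by AIC.
  marg_ll <- function(w) {
    L <- matrix(0, m, d + 1L)
    L[, 1] <- log(w[1]) + stats::dnorm(x, 0, sqrt(s), log = TRUE)
    for (u in seq_len(d))
      L[, u + 1L] <- log(w[u + 1L]) +
        stats::dnorm(x, mu[u], sqrt(s + ev[u]), log = TRUE)
    sum(logrowsums(L))
  }
  repeat {
    active <- which(w[-1] > 2 * floor_pi)
    if (!length(active)) break
    ll_full <- marg_ll(w)
    aic_drop <- vapply(active, function(u) {
      w2 <- w
      w2[1] <- w2[1] + w2[u + 1L] - floor_pi
      w2[u + 1L] <- floor_pi
      # folding removes 3 free parameters
      (2 * 3 - 2 * ll_full) - (-2 * marg_ll(w2 / sum(w2)))
    }, numeric(1))
    if (max(aic_drop) <= 0) break
    u <- active[which.max(aic_drop)]
    w[1] <- w[1] + w[u + 1L] - floor_pi
    w[u + 1L] <- floor_pi
    w <- w / sum(w)
  }

  list(weights = w, means = c(0, mu), extra_vars = c(0, ev),
       loglik = path[length(path)], loglik_path = path,
       converged = converged, responsibilities = R)
}

#' Choose the number of non-null mixture components by AIC
#'
#' Fits [fit_marginal_gmm()] for `d = 1, ..., d_max` and returns the `d`
#' minimizing \eqn{AIC = 2 p_d - 2\,\ell_d} with \eqn{p_d = 3d} free
#' parameters (d means, d extra variances, d free weights); ties go to the
#' smallest `d`.
#'
#' @inheritParams fit_marginal_gmm
#' @param d_max Largest candidate `d` (default 10).
#' @return Integer `d`, with attribute `aic` holding the full AIC path.
#' @export
select_components_aic <- function(values, variances, d_max = 10L,
                                  tol = 1e-8, max_iter = 1000L,
                                  n_restarts = 3L, seed = 1L) {
  stopifnot(d_max >= 1L)
  aic <- rep(NA_real_, d_max)
  for (d in seq_len(d_max)) {
    fit <- tryCatch(
      fit_marginal_gmm(values, variances, d, tol = tol, max_iter = max_iter,
                       n_restarts = n_restarts, seed = seed + d),
      error = function(e) {
        warning("marginal fit failed for d = ", d, ": ", conditionMessage(e))
        NULL
      })
    if (!is.null(fit)) aic[d] <- 2 * (3 * d) - 2 * fit$loglik
  }
  if (all(is.na(aic))) stop("all candidate fits failed", call. = FALSE)
  d_best <- which.min(aic)   # which.min takes the first (smallest d) on ties
  structure(as.integer(d_best), aic = aic)
}

#' Estimate joint mixing proportions with frozen marginal moments
#'
#' Step two of the two-step composite estimator: given fitted marginal
#' component moments for each axis, runs an EM over the full
#' \eqn{(d_1+1)(d_2+1)}-component bivariate grid in which all means and
#' variances are held fixed and only the joint proportion matrix
#' \eqn{\pi_{uv}} is updated. Initialized at the independence table (outer
#' product of the marginal weights).
#'
#' @param summary A [coef_summary()].
#' @param marg_a,marg_b Marginal fits from [fit_marginal_gmm()] for the
#'   `a` and `b` margins.
#' @param tol,max_iter EM controls.
#' @return A `composite_prior`: list with `mu`, `kappa` (a-margin means and
#'   extra variances, null first), `theta`, `psi` (b-margin), `pi`
#'   (`(d1+1) x (d2+1)` matrix), `d1`, `d2`, `marginal_weights_a/b`,
#'   `loglik`, `loglik_path`, `converged`.
#' @export
fit_joint_proportions <- function(summary, marg_a, marg_b,
                                  tol = 1e-8, max_iter = 1000L) {
  stopifnot(inherits(summary, "coef_summary"))
  d1 <- length(marg_a$means) - 1L
  d2 <- length(marg_b$means) - 1L
  prior <- structure(
    list(mu = marg_a$means, kappa = marg_a$extra_vars,
         theta = marg_b$means, psi = marg_b$extra_vars,
         pi = outer(marg_a$weights, marg_b$weights),
         d1 = d1, d2 = d2,
         marginal_weights_a = marg_a$weights,
         marginal_weights_b = marg_b$weights,
         loglik = NA_real_, loglik_path = numeric(0), converged = FALSE),
    class = "composite_prior")

  g <- prior_grid(prior)
  # Frozen per-unit component log-densities (without proportions).
  a <- summary$a; b <- summary$b
  s1 <- summary$var1; s2 <- summary$var2
  la <- matrix(vapply(seq_len(d1 + 1L), function(u)
    stats::dnorm(a, g$a_mean[u], sqrt(s1 + g$a_var[u]), log = TRUE),
    numeric(length(a))), nrow = length(a))
  lb <- matrix(vapply(seq_len(d2 + 1L), function(v)
    stats::dnorm(b, g$b_mean[v], sqrt(s2 + g$b_var[v]), log = TRUE),
    numeric(length(b))), nrow = length(b))
  K <- (d1 + 1L) * (d2 + 1L)
  ldens <- matrix(0, length(a), K)
  k <- 0L
  for (v in seq_len(d2 + 1L)) for (u in seq_len(d1 + 1L)) {
    k <- k + 1L
    ldens[, k] <- la[, u] + lb[, v]
  }

  piv <- as.numeric(prior$pi)
  floor_pi <- 1e-8
  path <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    L <- sweep(ldens, 2, log(pmax(piv, 1e-300)), `+`)
    mx <- apply(L, 1, max)
    R <- exp(L - mx)
    rs <- rowSums(R)
    ll <- sum(mx + log(rs))
    path <- c(path, ll)
    R <- R / rs
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-10)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    piv <- pmax(colMeans(R), floor_pi)
    piv <- piv / sum(piv)
  }

  prior$pi <- matrix(piv, d1 + 1L, d2 + 1L)
  prior$loglik <- path[length(path)]
  prior$loglik_path <- path
  prior$converged <- converged
  if (!converged) warning("joint-proportion EM did not converge")
  prior
}

#' Fit the composite-alternative prior by the two-step EM
#'
#' Convenience wrapper: fits the marginal mixtures on each axis (with AIC
#' selection of the component counts when `d1`/`d2` are `"auto"`), then
#' estimates the joint proportion table with moments frozen.
#'
#' @inheritParams fit_joint_proportions
#' @param d1,d2 Non-null component counts per margin, or `"auto"` for AIC
#'   selection up to `d_max`.
#' @param d_max Cap for AIC selection.
#' @param tol,max_iter,n_restarts,seed EM controls.
#' @return A `composite_prior` (see [fit_joint_proportions()]).
#' @export
composite_fit <- function(summary, d1 = "auto", d2 = "auto", d_max = 10L,
                          tol = 1e-8, max_iter = 1000L, n_restarts = 3L,
                          seed = 1L) {
  if (identical(d1, "auto"))
    d1 <- select_components_aic(summary$a, summary$var1, d_max, tol,
                                max_iter, n_restarts, seed)
  if (identical(d2, "auto"))
    d2 <- select_components_aic(summary$b, summary$var2, d_max, tol,
                                max_iter, n_restarts, seed + 1000L)
  marg_a <- fit_marginal_gmm(summary$a, summary$var1, as.integer(d1),
                             tol, max_iter, n_restarts, seed)
  marg_b <- fit_marginal_gmm(summary$b, summary$var2, as.integer(d2),
                             tol, max_iter, n_restarts, seed + 1L)
  fit_joint_proportions(summary, marg_a, marg_b, tol, max_iter)
}

#' @export
print.composite_prior <- function(x, ...) {
  cat("Composite-alternative mixture prior: d1 =", x$d1, ", d2 =", x$d2, "\n")
  cat("  a-margin means:", paste(sprintf("%.3f", x$mu), collapse = ", "), "\n")
  cat("  b-margin means:", paste(sprintf("%.3f", x$theta), collapse = ", "), "\n")
  cat(sprintf("  joint null mass = %.4f, loglik = %.4f (converged: %s)\n",
              sum(x$pi[1, ]) + sum(x$pi[, 1]) - x$pi[1, 1],
              x$loglik, x$converged))
  invisible(x)
}
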