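#' Fit the four-component bivariate mixture prior by EM
#'
#' Models the scaled coefficient pairs \eqn{(a_i, b_i)} as a four-component
#' bivariate Gaussian mixture indexed by the latent state
#' \eqn{\xi_i = (\xi_{i1}, \xi_{i2}) \in \{0,1\}^2}:
#' \deqn{a_i \mid \xi_i \sim N(\mu\,\xi_{i1},\; \sigma_{i1}^2 + \psi\,\xi_{i1}),
#'       \quad b_i \mid \xi_i \sim N(\theta\,\xi_{i2},\; \sigma_{i2}^2 + \kappa\,\xi_{i2}),}
#' independent given \eqn{\xi_i}, mixed over proportions
#' \eqn{\pi_{jk} = P(\xi_i = (j,k))}. The unit-specific sampling variances
#' \eqn{\sigma_{i1}^2, \sigma_{i2}^2} are treated as known (empirical-Bayes
#' plug-in); the five free parameters \eqn{\{\pi, \mu, \theta, \psi, \kappa\}}
#' are estimated by maximum likelihood via EM.
#'
#' Because the sampling variances differ across units, the M-step for
#' \eqn{(\mu, \psi)} has no closed form: it alternates the precision-weighted
#' mean update for \eqn{\mu} with a one-dimensional root solve for
#' \eqn{\psi \ge 0}; likewise for \eqn{(\theta, \kappa)}. When all units
#' share one sampling variance this reduces to the textbook closed form.
#'
#' @param summary A [coef_summary()] with at least 20 units.
#' @param init Optional `mixture_prior` used as the starting point for the
#'   first run; further restarts are jittered.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @param n_restarts Number of jittered restarts; the highest final
#'   log-likelihood wins.
#' @param seed Integer seed for the restart jitter (the fit is deterministic
#'   given the seed).
#' @return A `mixture_prior`: list with elements `pi` (2x2 matrix indexed by
#'   \eqn{(\xi_1, \xi_2)} states 0/1), `mu`, `psi`, `theta`, `kappa`,
#'   `loglik`, `loglik_path`, `converged`, `responsibilities` (m x 4, column
#'   order 00, 10, 01, 11).
#' @seealso [compute_lfdr()], [mlfdr_screen()]
#' @export
em_fit <- function(summary, init = NULL, tol = 1e-8, max_iter = 1000L,
                   n_restarts = 5L, seed = 1L) {
  stopifnot(inherits(summary, "coef_summary"))
  if (nrow(summary) < 20L)
    stop("need at least 20 units to fit the mixture", call. = FALSE)
  a <- summary$a; b <- summary$b
  s1 <- summary$var1; s2 <- summary$var2

  starts <- em_starts(a, b, s1, s2, n_restarts, seed, init)
  best <- NULL
  for (st in starts) {
    fit <- em_run(a, b, s1, s2, st, tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!best$converged)
    warning("EM did not converge within max_iter; returning best iterate")
  best
}

# Default and jittered starting points (restores the caller's RNG state).
em_starts <- function(a, b, s1, s2, n_restarts, seed, init = NULL) {
  mu0 <- trimmed_top_mean(a)
  th0 <- trimmed_top_mean(b)
  psi0 <- max(stats::var(a) - mean(s1), 0.1)
  kap0 <- max(stats::var(b) - mean(s2), 0.1)
  base <- list(pi = matrix(c(0.7, 0.1, 0.1, 0.1), 2, 2),
               mu = mu0, psi = psi0, theta = th0, kappa = kap0)
  if (!is.null(init))
    base <- list(pi = matrix(as.numeric(init$pi), 2, 2), mu = init$mu,
                 psi = init$psi, theta = init$theta, kappa = init$kappa)
  starts <- list(base)
  if (n_restarts > 1L) {
    starts <- c(starts, with_seed(seed, {
      lapply(seq_len(n_restarts - 1L), function(r) {
        p <- as.numeric(base$pi) * stats::runif(4, 0.5, 1.5)
        list(pi = matrix(p / sum(p), 2, 2),
             mu = base$mu * stats::runif(1, 0.5, 1.5) + stats::rnorm(1, 0, 0.1),
             psi = base$psi * stats::runif(1, 0.5, 2),
             theta = base$theta * stats::runif(1, 0.5, 1.5) + stats::rnorm(1, 0, 0.1),
             kappa = base$kappa * stats::runif(1, 0.5, 2))
      })
    }))
  }
  starts
}

# Trimmed mean of the top-decile |x| values, sign carried by the data.
trimmed_top_mean <- function(x) {
  idx <- abs(x) >= stats::quantile(abs(x), 0.9)
  mean(x[idx], trim = 0.1)
}

em_run <- function(a, b, s1, s2, st, tol, max_iter) {
  m <- length(a)
  pi <- st$pi; mu <- st$mu; psi <- st$psi; theta <- st$theta; kappa <- st$kappa
  floor_pi <- 1e-6
  path <- numeric(0)
  converged <- FALSE
  ll_old <- -Inf

  for (it in seq_len(max_iter)) {
    la0 <- stats::dnorm(a, 0, sqrt(s1), log = TRUE)
    la1 <- stats::dnorm(a, mu, sqrt(s1 + psi), log = TRUE)
    lb0 <- stats::dnorm(b, 0, sqrt(s2), log = TRUE)
    lb1 <- stats::dnorm(b, theta, sqrt(s2 + kappa), log = TRUE)
    # columns: 00, 10, 01, 11  (matches as.numeric of the 2x2 pi matrix)
    L <- cbind(log(pi[1, 1]) + la0 + lb0,
               log(pi[2, 1]) + la1 + lb0,
               log(pi[1, 2]) + la0 + lb1,
               log(pi[2, 2]) + la1 + lb1)
    mx <- pmax(L[, 1], L[, 2], L[, 3], L[, 4])
    R <- exp(L - mx)
    rs <- rowSums(R)
    ll <- sum(mx + log(rs))
    path <- c(path, ll)
    R <- R / rs

    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-10)) {
      converged <- TRUE
      break
    }
    ll_old <- ll

    p_new <- pmax(colMeans(R), floor_pi)
    p_new <- p_new / sum(p_new)
    pi <- matrix(p_new, 2, 2)

    up_a <- update_mean_var(a, s1, R[, 2] + R[, 4], mu, psi)
    mu <- up_a$mean; psi <- up_a$extra_var
    up_b <- update_mean_var(b, s2, R[, 1 + 2] + R[, 4], theta, kappa)
    theta <- up_b$mean; kappa <- up_b$extra_var
  }

  # Margin fold-back: near the null the likelihood is almost flat in how
  # mass splits between a margin's null and alternative states, so the EM
  # can park arbitrary null mass in an alternative that fits pure noise.
  # A margin keeps its alternative only if it earns its three parameters
  # (mean, extra variance, proportion) by AIC; otherwise its mass is
  # folded back into the null. This mirrors the AIC rule used for
  # composite-alternative component counts.
  fold <- choose_margin_fold(a, b, s1, s2, pi, mu, psi, theta, kappa,
                             floor_pi)
  pi <- fold$pi

  structure(list(pi = pi, mu = mu, psi = psi, theta = theta, kappa = kappa,
                 loglik = path[length(path)], loglik_path = path,
                 converged = converged, responsibilities = R,
                 folded = fold$folded),
            class = "mixture_prior")
}

# Evaluate the observed-data log-likelihood under the full prior and under
# the candidates that fold the a-margin, the b-margin, or both into their
# nulls; keep the AIC-best candidate. Folding a margin removes 3 free
# parameters.
choose_margin_fold <- function(a, b, s1, s2, pi, mu, psi, theta, kappa,
                               floor_pi) {
  fold_a <- function(p) {
    q <- matrix(c(p[1, 1] + p[2, 1] - floor_pi, floor_pi,
                  p[1, 2] + p[2, 2] - floor_pi, floor_pi), 2, 2)
    q / sum(q)
  }
  fold_b <- function(p) {
    q <- matrix(c(p[1, 1] + p[1, 2] - floor_pi, p[2, 1] + p[2, 2] - floor_pi,
                  floor_pi, floor_pi), 2, 2)
    q / sum(q)
  }
  cand <- list(none = pi, a = fold_a(pi), b = fold_b(pi),
               both = fold_b(fold_a(pi)))
  npar <- c(none = 7, a = 4, b = 4, both = 1)
  summ <- coef_summary(a, b, s1, s2, n = 2L)
  aic <- vapply(names(cand), function(nm) {
    pr <- structure(list(pi = cand[[nm]], mu = mu, psi = psi,
                         theta = theta, kappa = kappa),
                    class = "mixture_prior")
    2 * npar[[nm]] - 2 * loglik_mixture(summ, pr)
  }, numeric(1))
  best <- names(cand)[which.min(aic)]
  list(pi = cand[[best]], folded = best)
}

# M-step for one margin: maximize
#   Q(mean, v) = sum_i w_i [ -log(s_i + v)/2 - (x_i - mean)^2 / (2 (s_i + v)) ]
# over mean in R, v >= 0, by alternating the closed-form precision-weighted
# mean with a bounded 1-D root solve in v.
update_mean_var <- function(x, s, w, mean0, v0, inner_max = 8L) {
  mean <- mean0; v <- max(v0, 0)
  if (sum(w) < 1e-12) return(list(mean = mean0, extra_var = v0))
  for (j in seq_len(inner_max)) {
    prec <- w / (s + v)
    mean_new <- sum(prec * x) / sum(prec)
    v_new <- solve_extra_var(x, s, w, mean_new, v)
    if (abs(mean_new - mean) < 1e-9 * (1 + abs(mean)) &&
        abs(v_new - v) < 1e-9 * (1 + v)) {
      mean <- mean_new; v <- v_new
      break
    }
    mean <- mean_new; v <- v_new
  }
  list(mean = mean, extra_var = v)
}

# Root of g(v) = sum_i w_i ((x_i - mean)^2 - (s_i + v)) / (s_i + v)^2 on
# v >= 0 (the stationarity condition in v). g(0) <= 0 pins v at the boundary.
solve_extra_var <- function(x, s, w, mean, v_start) {
  g <- function(v) {
    vi <- s + v
    sum(w * ((x - mean)^2 - vi) / vi^2)
  }
  if (g(0) <= 0) return(0)
  hi <- max(v_start, 1)
  while (g(hi) > 0 && hi < 1e8) hi <- hi * 2
  if (g(hi) > 0) return(hi)
  stats::uniroot(g, c(0, hi), tol = 1e-9)$root
}

#' Observed-data log-likelihood of a mixture prior
#'
#' Computes \eqn{\sum_i \log f(a_i, b_i)} where `f` is the full mixture
#' density implied by the prior (simple or composite), evaluated in
#' log-space with a log-sum-exp over components.
#'
#' @param summary A [coef_summary()].
#' @param prior A `mixture_prior` or `composite_prior`.
#' @return Scalar log-likelihood.
#' @export
loglik_mixture <- function(summary, prior) {
  g <- prior_grid(prior)
  ld <- component_logdens(summary, g)
  sum(logrowsums(ld$all))
}

# Common component-grid representation: a-margin means/extra-variances over
# u = 0..d1 (component 0 is the null, pinned at mean 0, extra variance 0),
# b-margin over v = 0..d2, and the joint proportion matrix.
prior_grid <- function(prior) {
  if (inherits(prior, "mixture_prior")) {
    list(a_mean = c(0, prior$mu), a_var = c(0, prior$psi),
         b_mean = c(0, prior$theta), b_var = c(0, prior$kappa),
         pi = prior$pi)
  } else if (inherits(prior, "composite_prior")) {
    list(a_mean = prior$mu, a_var = prior$kappa,
         b_mean = prior$theta, b_var = prior$psi,
         pi = prior$pi)
  } else stop("unknown prior class", call. = FALSE)
}

# Per-unit log joint component densities log(pi_uv f_uv(a_i, b_i)):
# returns the m x (d1+1)(d2+1) matrix plus the null-component column mask.
component_logdens <- function(summary, g) {
  a <- summary$a; b <- summary$b
  s1 <- summary$var1; s2 <- summary$var2
  d1p <- length(g$a_mean); d2p <- length(g$b_mean)
  la <- matrix(vapply(seq_len(d1p), function(u)
    stats::dnorm(a, g$a_mean[u], sqrt(s1 + g$a_var[u]), log = TRUE),
    numeric(length(a))), nrow = length(a))
  lb <- matrix(vapply(seq_len(d2p), function(v)
    stats::dnorm(b, g$b_mean[v], sqrt(s2 + g$b_var[v]), log = TRUE),
    numeric(length(b))), nrow = length(b))
  K <- d1p * d2p
  out <- matrix(0, length(a), K)
  null_mask <- logical(K)
  k <- 0L
  lpi <- log(pmax(g$pi, 1e-300))
  for (v in seq_len(d2p)) for (u in seq_len(d1p)) {
    k <- k + 1L
    out[, k] <- lpi[u, v] + la[, u] + lb[, v]
    null_mask[k] <- (u == 1L) || (v == 1L)
  }
  list(all = out, null_mask = null_mask)
}

logrowsums <- function(L) {
  L <- matrix(L, nrow = NROW(L))
  mx <- apply(L, 1, max)
  mx + log(rowSums(exp(L - mx)))
}

#' @export
print.mixture_prior <- function(x, ...) {
  p <- as.numeric(x$pi)
  cat("Bivariate mixture prior (simple alternative)\n")
  cat(sprintf("  pi(00,10,01,11) = (%.4f, %.4f, %.4f, %.4f)\n",
              p[1], p[2], p[3], p[4]))
  cat(sprintf("  a-margin: mu = %.4f, psi = %.4f\n", x$mu, x$psi))
  cat(sprintf("  b-margin: theta = %.4f, kappa = %.4f\n", x$theta, x$kappa))
  cat(sprintf("  loglik = %.4f after %d iterations (converged: %s)\n",
              x$loglik, length(x$loglik_path), x$converged))
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
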