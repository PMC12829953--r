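#' Fit the per-unit structural equation models
#'
#' For each unit `i`, fits the mediator model (regress \eqn{M_i} on an
#' intercept, the exposure and any covariates) and the outcome model
#' (regress \eqn{Y_i} on an intercept, \eqn{M_i}, the exposure and the
#' covariates; logistic maximum likelihood when the outcome is binary), and
#' returns the root-n scaled coefficient estimates and their variances.
#'
#' The exposure coefficient of the mediator model is \eqn{\hat\alpha_i}; the
#' mediator coefficient of the outcome model is \eqn{\hat\beta_i}.
#' Conditional on the design, the two estimators are independent with
#' variances estimated by the usual OLS formulas (residual variance
#' \eqn{RSS/(n-p)}), or by the inverse Fisher information for logistic
#' outcomes. An intercept is always included.
#'
#' @param data A [mediation_dataset()].
#' @param extra_mediator_design,extra_outcome_design Optional `n x k`
#'   matrices of additional columns appended to the mediator and outcome
#'   designs (used by the latent-factor adjustment).
#' @return A [coef_summary()].
#' @export
#' @examples
#' set.seed(1)
#' X <- rbinom(80, 1, 0.5)
#' M <- outer(X, c(1, 0)) + matrix(rnorm(160), 80, 2)
#' Y <- M %*% diag(c(0.8, 0)) + matrix(rnorm(160), 80, 2)
#' fit_structural_models(mediation_dataset(X, M, Y))
fit_structural_models <- function(data,
                                  extra_mediator_design = NULL,
                                  extra_outcome_design = NULL) {
  stopifnot(inherits(data, "mediation_dataset"))
  n <- data$n
  m <- data$m
  Z <- data$covariates
  unit_exposure <- is.matrix(data$exposure)

  base_cols <- cbind(`(Intercept)` = rep(1, n), Z)
  k_med <- if (is.null(extra_mediator_design)) 0L else ncol(extra_mediator_design)
  k_out <- if (is.null(extra_outcome_design)) 0L else ncol(extra_outcome_design)
  p_med <- ncol(base_cols) + 1L + k_med
  p_out <- ncol(base_cols) + 2L + k_med + k_out
  if (n <= max(p_med, p_out))
    stop("sample size too small for the regression designs", call. = FALSE)

  a <- b <- var1 <- var2 <- numeric(m)

  # Mediator model: with a shared exposure the design is common to all
  # units, so all m responses are solved in one least-squares call.
  if (!unit_exposure) {
    Xd <- cbind(base_cols, exposure = data$exposure, extra_mediator_design)
    med <- ols_multi(Xd, data$mediators, coef_col = ncol(base_cols) + 1L)
    alpha_hat <- med$coef
    alpha_var <- med$var
    resid_var_M <- med$sigma2
  }

  for (i in seq_len(m)) {
    Mi <- data$mediators[, i]
    if (unit_exposure) {
      Xd <- cbind(base_cols, exposure = data$exposure[, i],
                  extra_mediator_design)
      fit <- ols_single(Xd, Mi, coef_col = ncol(base_cols) + 1L,
                        unit = data$unit_ids[i])
      alpha_hat_i <- fit$coef
      alpha_var_i <- fit$var
      if (fit$sigma2 < 1e-12)
        stop("degenerate (zero residual variance) mediator for unit ",
             data$unit_ids[i], call. = FALSE)
    } else {
      alpha_hat_i <- alpha_hat[i]
      alpha_var_i <- alpha_var[i]
      if (resid_var_M[i] < 1e-12)
        stop("degenerate (zero residual variance) mediator for unit ",
             data$unit_ids[i], call. = FALSE)
    }

    Yi <- if (data$shared_outcome) data$outcomes else data$outcomes[, i]
    Xe <- if (unit_exposure) data$exposure[, i] else data$exposure
    Yd <- cbind(base_cols, mediator = Mi, exposure = Xe,
                extra_mediator_design, extra_outcome_design)
    mcol <- ncol(base_cols) + 1L
    if (data$outcome_type == "binary") {
      fit <- logistic_fit(Yd, Yi, coef_col = mcol, unit = data$unit_ids[i])
    } else {
      fit <- ols_single(Yd, Yi, coef_col = mcol, unit = data$unit_ids[i])
    }
    a[i] <- sqrt(n) * alpha_hat_i
    b[i] <- sqrt(n) * fit$coef
    var1[i] <- n * alpha_var_i
    var2[i] <- n * fit$var
  }

  coef_summary(a, b, var1, var2, n = n, unit_ids = data$unit_ids)
}

# Multi-response OLS with a shared design; returns the requested
# coefficient, its variance and the residual variance per response.
ols_multi <- function(X, Y, coef_col) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("singular design matrix in the mediator model", call. = FALSE)
  cf <- qr.coef(qrX, Y)
  res <- Y - X %*% cf
  dfree <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / dfree
  jj <- which(qrX$pivot == coef_col)
  XtXinv_jj <- chol2inv(qr.R(qrX))[jj, jj]
  list(coef = cf[coef_col, ], var = sigma2 * XtXinv_jj, sigma2 = sigma2)
}

ols_single <- function(X, y, coef_col, unit = "?") {
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("singular design matrix for unit ", unit, call. = FALSE)
  cf <- qr.coef(qrX, y)
  res <- y - drop(X %*% cf)
  sigma2 <- sum(res^2) / (nrow(X) - ncol(X))
  jj <- which(qrX$pivot == coef_col)
  XtXinv_jj <- chol2inv(qr.R(qrX))[jj, jj]
  list(coef = cf[coef_col], var = sigma2 * XtXinv_jj, sigma2 = sigma2)
}

# Logistic ML by Newton-Raphson (IRLS); tolerance on the log-likelihood,
# capped iterations, with a divergence check for separation.
logistic_fit <- function(X, y, coef_col, unit = "?",
                         tol = 1e-8, max_iter = 100L) {
  p <- ncol(X)
  beta <- numeric(p)
  ll_old <- -Inf
  sds <- apply(X, 2, stats::sd)
  sds[sds < 1e-12] <- 1
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    if (any(w < 1e-12)) w <- pmax(w, 1e-12)
    XtWX <- crossprod(X * sqrt(w))
    score <- crossprod(X, y - mu)
    step <- tryCatch(solve(XtWX, score),
                     error = function(e)
                       stop("singular design matrix for unit ", unit,
                            call. = FALSE))
    beta <- beta + drop(step)
    if (any(abs(beta * sds) > 50))
      stop("logistic separation (diverging coefficients) for unit ", unit,
           call. = FALSE)
    eta <- drop(X %*% beta)
    ll <- sum(y * eta - log1p(exp(eta)))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-10))
      break
    if (it == max_iter)
      stop("logistic fit did not converge for unit ", unit, call. = FALSE)
    ll_old <- ll
  }
  mu <- stats::plogis(drop(X %*% beta))
  w <- pmax(mu * (1 - mu), 1e-12)
  cov <- solve(crossprod(X * sqrt(w)))
  list(coef = beta[coef_col], var = cov[coef_col, coef_col])
}
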