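#' Estimate surrogate factors from residual principal components
#'
#' Residualizes every column of a high-dimensional matrix (mediators, or
#' outcomes with the mediators excluded) on an intercept, the exposure and
#' any measured covariates, column-standardizes the residual matrix, and
#' returns the top left singular vectors as orthonormal surrogate factor
#' scores. These span the structured unmeasured variation — batch effects,
#' unmeasured confounders, dense pleiotropy — that would otherwise bias the
#' per-unit coefficient estimates.
#'
#' When `k = "auto"`, the dimension is chosen by a permutation (parallel
#' analysis) rule: each singular value is kept while it exceeds the 95th
#' percentile of the corresponding singular values of `B` matrices whose
#' columns have been independently permuted (which destroys cross-column
#' structure but keeps the column distributions).
#'
#' @param Y_like Numeric `n x m` matrix whose columns carry a shared latent
#'   structure.
#' @param X Exposure vector (length `n`), or `NULL`.
#' @param Z Optional `n x q` covariate matrix.
#' @param k Number of factors, or `"auto"`.
#' @param k_max Cap on the number of factors (default 10).
#' @param B Number of permutation draws for the auto rule.
#' @param seed Seed for the permutations.
#' @return An `n x k` matrix with orthonormal columns (possibly `k = 0`),
#'   with attributes `singular_values` and `perm_quantiles`.
#' @export
estimate_surrogates <- function(Y_like, X = NULL, Z = NULL, k = "auto",
                                k_max = 10L, B = 20L, seed = 1L) {
  Y_like <- as.matrix(Y_like)
  n <- nrow(Y_like); m <- ncol(Y_like)
  if (m < 2L) stop("need at least 2 columns", call. = FALSE)
  design <- cbind(rep(1, n), X, Z)
  if (n <= ncol(design) + 1L) stop("too few samples to residualize", call. = FALSE)
  if (is.numeric(k) && k > min(n, m))
    stop("k cannot exceed min(n, m)", call. = FALSE)

  qrD <- qr(design)
  R <- Y_like - qr.fitted(qrD, Y_like)
  sds <- sqrt(colSums(R^2) / (n - 1))
  keep <- sds > 1e-10
  if (!any(keep)) {
    out <- matrix(0, n, 0)
    attr(out, "singular_values") <- numeric(0)
    return(out)
  }
  Rs <- sweep(R[, keep, drop = FALSE], 2, sds[keep], `/`)

  k_cap <- min(k_max, n - ncol(design) - 1L, sum(keep))
  sv <- svals(Rs, k_cap)

  if (identical(k, "auto")) {
    perm_q <- with_seed(seed, {
      P <- vapply(seq_len(B), function(b) {
        Rp <- apply(Rs, 2, sample)
        # permuted columns must be re-residualized on the same design and
        # re-standardized so their scale matches the observed matrix
        Rp <- Rp - qr.fitted(qrD, Rp)
        sdp <- sqrt(colSums(Rp^2) / (n - 1))
        Rp <- sweep(Rp, 2, pmax(sdp, 1e-12), `/`)
        svals(Rp, k_cap)
      }, numeric(k_cap))
      apply(matrix(P, nrow = k_cap), 1, stats::quantile, probs = 0.95)
    })
    exceeds <- sv > perm_q
    k <- if (all(exceeds)) k_cap else (which.min(exceeds) - 1L)
  } else {
    perm_q <- NULL
    k <- as.integer(k)
  }

  U <- if (k > 0L) {
    # The factor subspace (loadings) is identified from the residuals, but
    # the scores are taken by projecting the standardized *raw* data onto
    # those loadings: residual-only scores are orthogonal to the exposure
    # by construction, so they could never remove the part of a latent
    # confounder that is correlated with the exposure in-sample; the
    # raw-data projection retains that component, and the downstream
    # regression then adjusts for it.
    V <- svd(Rs, nu = 0, nv = k)$v[, seq_len(k), drop = FALSE]
    raw_std <- sweep(sweep(Y_like[, keep, drop = FALSE], 2,
                           colMeans(Y_like[, keep, drop = FALSE])),
                     2, sds[keep], `/`)
    scores <- raw_std %*% V
    qr.Q(qr(scores))[, seq_len(k), drop = FALSE]
  } else matrix(0, n, 0)
  attr(U, "singular_values") <- sv
  attr(U, "perm_quantiles") <- perm_q
  U
}

# Top-k singular values via the small-side Gram matrix.
svals <- function(A, k) {
  G <- if (nrow(A) <= ncol(A)) tcrossprod(A) else crossprod(A)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  sqrt(pmax(ev[seq_len(k)], 0))
}

#' Refit the structural models with surrogate-factor adjustment
#'
#' Runs the full two-step global adjustment: the mediator-derived factors
#' `U_M` enter both the mediator and outcome models; the outcome-derived
#' factors `U_Y` enter only the outcome model. With zero factors on both
#' sides this reduces exactly to [fit_structural_models()].
#'
#' @param data A [mediation_dataset()].
#' @param U_M `n x k_M` factor matrix from the mediator residuals (may have
#'   zero columns).
#' @param U_Y `n x k_Y` factor matrix from the outcome null-model residuals.
#' @return A [coef_summary()] of adjusted scaled estimates.
#' @export
adjusted_mediation_fit <- function(data, U_M, U_Y) {
  stopifnot(inherits(data, "mediation_dataset"))
  U_M <- as.matrix(U_M); U_Y <- as.matrix(U_Y)
  if ((ncol(U_M) && nrow(U_M) != data$n) || (ncol(U_Y) && nrow(U_Y) != data$n))
    stop("factor matrices must have n rows", call. = FALSE)
  fit_structural_models(
    data,
    extra_mediator_design = if (ncol(U_M)) U_M else NULL,
    extra_outcome_design = if (ncol(U_Y)) U_Y else NULL)
}

#' Full adjusted pipeline: factors, refit, summary
#'
#' Convenience wrapper implementing the two-step global factor adjustment
#' end to end: estimate `U_M` from mediator residuals and `U_Y` from
#' outcome null-model residuals, then refit every unit with the factors
#' appended.
#'
#' @param data A [mediation_dataset()] with per-unit outcomes.
#' @param k_M,k_Y Factor counts or `"auto"`.
#' @param k_max,B,seed Passed to [estimate_surrogates()].
#' @return A [coef_summary()] with attributes `U_M`, `U_Y`.
#' @export
latent_adjusted_summary <- function(data, k_M = "auto", k_Y = "auto",
                                    k_max = 10L, B = 20L, seed = 1L) {
  X <- if (is.matrix(data$exposure)) NULL else data$exposure
  U_M <- estimate_surrogates(data$mediators, X, data$covariates,
                             k = k_M, k_max = k_max, B = B, seed = seed)
  Ymat <- if (data$shared_outcome) matrix(data$outcomes, ncol = 1) else data$outcomes
  U_Y <- if (ncol(Ymat) >= 2L) {
    estimate_surrogates(Ymat, X, data$covariates, k = k_Y, k_max = k_max,
                        B = B, seed = seed + 1L)
  } else matrix(0, data$n, 0)
  out <- adjusted_mediation_fit(data, U_M, U_Y)
  attr(out, "U_M") <- U_M
  attr(out, "U_Y") <- U_Y
  out
}
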