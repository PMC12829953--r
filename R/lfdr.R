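#' Composite-null local false discovery rate
#'
#' For each unit, the posterior probability that the composite null
#' \eqn{\alpha_i \beta_i = 0} holds given the observed scaled estimates:
#' \deqn{\mathrm{lfdr}(a_i, b_i) =
#'   \frac{\sum_{(u,v): u = 0 \,\mathrm{or}\, v = 0} \pi_{uv} f_{uv}(a_i, b_i)}
#'        {\sum_{u,v} \pi_{uv} f_{uv}(a_i, b_i)},}
#' where \eqn{f_{uv}} are zero-correlation bivariate normal component
#' densities with unit-specific variances. Evaluated in log-space and
#' clipped to `[0, 1]`.
#'
#' @param summary A [coef_summary()].
#' @param prior A `mixture_prior` from [em_fit()] or a `composite_prior`
#'   from [composite_fit()]; any prior with proportions, component means
#'   and extra variances.
#' @return Numeric vector of lfdr values in `[0, 1]`.
#' @export
compute_lfdr <- function(summary, prior) {
  stopifnot(inherits(summary, "coef_summary"))
  if (any(!is.finite(summary$a)) || any(!is.finite(summary$b))) {
    bad <- which(!is.finite(summary$a) | !is.finite(summary$b))[1]
    stop("non-finite statistic for unit ", summary$unit_id[bad], call. = FALSE)
  }
  g <- prior_grid(prior)
  ld <- component_logdens(summary, g)
  log_all <- logrowsums(ld$all)
  log_null <- logrowsums(ld$all[, ld$null_mask, drop = FALSE])
  pmin(pmax(exp(log_null - log_all), 0), 1)
}

#' Adaptive step-up screening on lfdr values
#'
#' Sorts the lfdr values ascending and rejects the largest prefix whose
#' running mean stays at or below the nominal level `alpha`; the realized
#' threshold is the k-th order statistic. The running mean of the k
#' smallest lfdr values estimates the marginal FDR of rejecting exactly
#' those k hypotheses, so the procedure rejects as much as possible while
#' the estimate remains controlled.
#'
#' @param lfdr Numeric vector of lfdr values in `[0, 1]`.
#' @param alpha Nominal FDR level in (0, 1).
#' @param ties `"stable"` (default) treats tied lfdr values as one block
#'   (rejected or kept together, which makes the procedure identical to
#'   the sup-form threshold); `"random"` shuffles units first (seeded) and
#'   rejects exactly the k smallest in shuffled order.
#' @param seed Seed used only when `ties = "random"`.
#' @return An `lfdr_screen_result`: list with `lfdr`, `order`,
#'   `running_mean`, `k_reject`, `delta_hat`, `rejected` (logical),
#'   `alpha`.
#' @export
#' @examples
#' step_up(c(0.01, 0.02, 0.10, 0.30), alpha = 0.05)$k_reject  # 3
step_up <- function(lfdr, alpha, ties = c("stable", "random"), seed = 1L) {
  ties <- match.arg(ties)
  if (any(lfdr < 0 | lfdr > 1) || anyNA(lfdr))
    stop("lfdr values must lie in [0, 1]", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1)
  m <- length(lfdr)
  idx <- seq_len(m)
  if (ties == "random") idx <- with_seed(seed, sample.int(m))
  ord <- idx[order(lfdr[idx], method = "radix")]
  sorted <- lfdr[ord]
  run_mean <- cumsum(sorted) / seq_len(m)
  feasible <- run_mean <= alpha
  if (ties == "stable") {
    # a threshold rule cannot split a block of tied lfdr values, so the
    # cutoff index must close its tie block; this makes the procedure
    # coincide exactly with the sup-form threshold of the mFDR estimate
    feasible <- feasible & c(sorted[-m] < sorted[-1], TRUE)
  }
  k <- if (any(feasible)) max(which(feasible)) else 0L
  delta_hat <- if (k > 0L) lfdr[ord[k]] else 0
  rejected <- logical(m)
  if (k > 0L) rejected[ord[seq_len(k)]] <- TRUE
  structure(list(lfdr = lfdr, order = ord, running_mean = run_mean,
                 k_reject = k, delta_hat = delta_hat, rejected = rejected,
                 alpha = alpha),
            class = "lfdr_screen_result")
}

#' Sup-form threshold for the step-up procedure
#'
#' Direct evaluation of the defining threshold
#' \eqn{\hat\delta_m = \sup\{t : \hat Q_m(t) \le \alpha\}} with
#' \eqn{\hat Q_m(t)} the average lfdr among units with lfdr at most `t`,
#' scanned over the observed lfdr values (the only points where
#' \eqn{\hat Q_m} changes). Exists as an independent cross-check of
#' [step_up()].
#'
#' @inheritParams step_up
#' @return The threshold, or `NA_real_` when no candidate satisfies the
#'   constraint (no rejections).
#' @export
threshold_sup_form <- function(lfdr, alpha) {
  if (any(lfdr < 0 | lfdr > 1) || anyNA(lfdr))
    stop("lfdr values must lie in [0, 1]", call. = FALSE)
  cand <- sort(unique(lfdr))
  Q <- vapply(cand, function(t) {
    sel <- lfdr <= t
    sum(lfdr[sel]) / sum(sel)
  }, numeric(1))
  feasible <- cand[Q <= alpha]
  if (!length(feasible)) return(NA_real_)
  max(feasible)
}

#' Oracle counting-process diagnostics on simulated data
#'
#' Given lfdr values and the simulation truth, evaluates on a grid of
#' thresholds the false rejections \eqn{V_m}, total rejections \eqn{R_m},
#' missed discoveries \eqn{P_m}, the lfdr mass of the rejection set
#' \eqn{W_m = \sum_i 1\{lfdr_i \le \delta\} lfdr_i}, the empirical cdf
#' \eqn{G} of the lfdr and its per-state versions \eqn{G_{jk}}, and the
#' plug-in mFDR estimate \eqn{Q_m = W_m / R_m}. Used in tests and
#' benchmarks only.
#'
#' @param lfdr Numeric lfdr vector.
#' @param truth A `sim_truth` (see [generate_scenario()]).
#' @param grid Thresholds at which to evaluate (default: sorted lfdr).
#' @return A data.frame with one row per grid point.
#' @export
oracle_diagnostics <- function(lfdr, truth, grid = NULL) {
  if (is.null(grid)) grid <- sort(unique(lfdr))
  xi1 <- truth$xi[, 1] > 0
  xi2 <- truth$xi[, 2] > 0
  is_alt <- xi1 & xi2
  m <- length(lfdr)
  states <- list(`00` = !xi1 & !xi2, `10` = xi1 & !xi2,
                 `01` = !xi1 & xi2, `11` = is_alt)
  rows <- lapply(grid, function(d) {
    sel <- lfdr <= d
    out <- data.frame(delta = d,
                      Vm = sum(sel & !is_alt),
                      Rm = sum(sel),
                      Pm = sum(!sel & is_alt),
                      Wm = sum(lfdr[sel]),
                      G = mean(sel))
    for (s in names(states)) {
      ns <- sum(states[[s]])
      out[[paste0("G", s)]] <- if (ns) sum(sel & states[[s]]) / ns else NA_real_
    }
    out$Qm <- if (out$Rm > 0) out$Wm / out$Rm else NA_real_
    out
  })
  do.call(rbind, rows)
}

#' One-call screening: mixture fit plus step-up thresholding
#'
#' Fits the prior (simple four-component model by default, or the
#' composite-alternative model) on a coefficient summary and applies the
#' adaptive step-up procedure at level `alpha`.
#'
#' @param summary A [coef_summary()].
#' @param alpha Nominal FDR level.
#' @param model `"simple"` or `"composite"`.
#' @param prior Optional pre-fitted prior (skips estimation; this is how an
#'   oracle analysis supplies the true parameters).
#' @param d1,d2,d_max Composite-model component counts (see
#'   [composite_fit()]).
#' @param em_tol,em_max_iter,n_restarts,seed EM controls.
#' @return An `lfdr_screen_result` with the fitted `prior` attached.
#' @export
mlfdr_screen <- function(summary, alpha = 0.05,
                         model = c("simple", "composite"), prior = NULL,
                         d1 = "auto", d2 = "auto", d_max = 10L,
                         em_tol = 1e-8, em_max_iter = 1000L,
                         n_restarts = 5L, seed = 1L) {
  model <- match.arg(model)
  if (is.null(prior)) {
    prior <- if (model == "simple") {
      em_fit(summary, tol = em_tol, max_iter = em_max_iter,
             n_restarts = n_restarts, seed = seed)
    } else {
      composite_fit(summary, d1 = d1, d2 = d2, d_max = d_max, tol = em_tol,
                    max_iter = em_max_iter, n_restarts = n_restarts,
                    seed = seed)
    }
  }
  lf <- compute_lfdr(summary, prior)
  res <- step_up(lf, alpha)
  res$prior <- prior
  res$unit_id <- summary$unit_id
  res
}

#' @export
print.lfdr_screen_result <- function(x, ...) {
  cat("lfdr step-up screen at alpha =", x$alpha, "\n")
  cat("  m =", length(x$lfdr), "units;", x$k_reject, "rejected;",
      "threshold =", format(x$delta_hat, digits = 4), "\n")
  invisible(x)
}

#' Export a screening result as a table
#'
#' @param result An `lfdr_screen_result` (from [mlfdr_screen()]).
#' @param summary The [coef_summary()] that was screened.
#' @return Data.frame with columns `unit_id`, `a`, `b`, `lfdr`, `rank`,
#'   `rejected`.
#' @export
screen_table <- function(result, summary) {
  rank <- integer(length(result$lfdr))
  rank[result$order] <- seq_along(result$lfdr)
  data.frame(unit_id = summary$unit_id, a = summary$a, b = summary$b,
             lfdr = result$lfdr, rank = rank, rejected = result$rejected)
}
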