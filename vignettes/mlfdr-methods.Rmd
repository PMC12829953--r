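---
title: "Screening mediation effects with composite-null local false discovery rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening mediation effects with composite-null local false discovery rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In genome-wide mediation screens — SNPs acting on gene expression through
CpG methylation, or smoking acting on expression through methylation — each
candidate pathway $i$ carries two regression coefficients: the
exposure-to-mediator slope $\alpha_i$ and the mediator-to-outcome slope
$\beta_i$. A pathway mediates only if **both** are nonzero, so the null
hypothesis is the composite

$$H_{0,i}:\ \alpha_i \beta_i = 0
  \;=\; H_{00,i} \cup H_{10,i} \cup H_{01,i},$$

the union of "both zero", "$\alpha$ only", and "$\beta$ only". Classical
tests (Sobel, max-P) calibrate against the boundary cases and are badly
conservative when most units sit at $H_{00}$, which is the norm in omics
panels. `mlfdr` instead works in the two-group empirical-Bayes tradition:
it puts a mixture prior over the four latent states, computes each unit's
posterior probability of being null — its local false discovery rate — and
thresholds that quantity directly.

## Model

For each unit, ordinary least squares (logistic maximum likelihood for
binary outcomes) on

$$M_i = \mu_i + \alpha_i X + \phi_i' Z + e_i, \qquad
  Y_i = \nu_i + \beta_i M_i + \gamma_i X + \delta_i' Z + \epsilon_i$$

yields $\hat\alpha_i, \hat\beta_i$, which are conditionally independent
given the design. The package works throughout on the $\sqrt{n}$ scale,
$a_i = \sqrt{n}\,\hat\alpha_i$, $b_i = \sqrt{n}\,\hat\beta_i$, with
conditional variances $\sigma_{i1}^2 = n\,\mathrm{Var}(\hat\alpha_i)$,
$\sigma_{i2}^2 = n\,\mathrm{Var}(\hat\beta_i)$ treated as known
(empirical-Bayes plug-in; estimation error in the variances is ignored).
Intercepts are always included, and residual variances use the unbiased
$RSS/(n-p)$.

With latent states $\xi_i = (\xi_{i1}, \xi_{i2}) \in \{0,1\}^2$,
$P(\xi_i = (j,k)) = \pi_{jk}$, and normal priors on the nonzero effects,

$$\binom{a_i}{b_i}\,\Big|\,\xi_i \sim
  N\!\left(\binom{\mu\,\xi_{i1}}{\theta\,\xi_{i2}},\;
  \mathrm{diag}(\sigma_{i1}^2 + \psi\,\xi_{i1},\,
                \sigma_{i2}^2 + \kappa\,\xi_{i2})\right),$$

a four-component bivariate Gaussian mixture whose five free parameters
$\{\pi, \mu, \psi, \theta, \kappa\}$ are estimated by EM (`em_fit()`). The
local fdr is the posterior null probability

$$\mathrm{lfdr}(a_i, b_i) =
  \frac{\pi_{00} f_{00} + \pi_{10} f_{10} + \pi_{01} f_{01}}
       {\sum_{j,k} \pi_{jk} f_{jk}}(a_i, b_i),$$

evaluated in log space and clipped to $[0,1]$. Rejection uses a step-up
scan (`step_up()`): sort the lfdr values, find the largest prefix whose
running mean stays at or below the nominal level $\alpha$, and reject that
prefix. The running mean of the rejected lfdrs is an estimate of the
marginal FDR of that rejection set, so the procedure rejects as much as
possible subject to the estimate staying controlled; `threshold_sup_form()`
evaluates the equivalent sup-form threshold and exists purely as a
cross-check.

## EM details and numerical choices

* **Heteroscedastic M-step.** With unit-specific $\sigma_{i1}^2$ there is
  no closed form for $(\mu, \psi)$; the M-step alternates the
  precision-weighted mean update with a bounded Brent root solve for
  $\psi \ge 0$ (at most 8 alternations — the pair converges in a handful).
  When all variances are equal this reduces to the textbook closed form,
  which the tests use as an oracle.
* **Initialization and restarts.** $\pi^0 = (0.7, 0.1, 0.1, 0.1)$;
  $\mu^0, \theta^0$ are 10%-trimmed means of the top-decile $|a|$, $|b|$;
  $\psi^0, \kappa^0 = \max(\mathrm{var} - \overline{\sigma^2}, 0.1)$.
  Additional restarts (default 5) jitter these; the best final
  log-likelihood wins. The restart RNG is seeded explicitly and restored
  afterwards.
* **Convergence.** Relative log-likelihood change below `tol` (default
  1e-8) or 1000 iterations. Near-null ridges drift extremely slowly, so
  large simulation studies in this package run with `tol = 1e-7`, which
  typically stops within a few dozen iterations at visually identical
  estimates.
* **Proportion floor.** Components are floored at 1e-6 and renormalized so
  the lfdr stays well defined; densities are floored at 1e-300 before
  ratios.
* **AIC fold-back.** Near the null the likelihood is nearly flat in how
  mass splits between a margin's null and an alternative component sitting
  on top of it, so the EM can park arbitrary null mass in a degenerate
  alternative and later mistake it for signal. After convergence each
  margin's alternative is kept only if it earns its three parameters
  (mean, extra variance, proportion) by AIC; otherwise its mass folds back
  into the null. The same greedy rule is applied per component in the
  univariate fits. On global-null data this sends $\hat\pi_{00} \to 1$ and
  the screen rejects nothing, as it should.
* **Ties.** Tied lfdr values are treated as one block — rejected or kept
  together — which makes the step-up scan coincide exactly with the
  sup-form threshold on every input. A seeded `ties = "random"` variant
  reproduces the randomized tie-break instead.

## Composite alternatives

When the effect-size distributions are themselves mixtures, each margin is
modeled as a null-pinned univariate mixture with $d_1$ (resp. $d_2$)
non-null components (`fit_marginal_gmm()`), with $d$ chosen by AIC
(`select_components_aic()`; penalty $2 p_d$ with $p_d = 3d$, ties to the
smaller $d$, default cap 10). Fitting the full
$(d_1+1)(d_2+1)$-component bivariate mixture is avoided by the two-step
estimator: marginal moments first, then a constrained EM that re-estimates
only the joint proportion table, started at the independence table
(`fit_joint_proportions()`). Only the joint table is updated in step two;
the step-one marginal weights are kept as diagnostics. Under the composite
prior the null region is every component pair with $u = 0$ or $v = 0$, and
`compute_lfdr()` reduces exactly to the simple model when
$d_1 = d_2 = 1$. The two-step route trades a small amount of power for a
large computational saving; in the bundled checks its rejection set
differs from the standard EM's by well under 2% when both fit the same
single-alternative data.

## Latent-factor adjustment

Unmeasured confounders, batch structure and dense pleiotropy (other
mediators feeding the same outcome) all manifest as shared low-rank
structure across units. `latent_adjusted_summary()` adjusts for it in two
steps: estimate factors $\hat U^M$ from the mediator matrix and
$\hat U^Y$ from the outcome matrix with mediators excluded, then refit
every unit with $\hat U^M$ in both models and $\hat U^Y$ in the outcome
model only.

Factor estimation (`estimate_surrogates()`) residualizes each column on
$[1, X, Z]$, column-standardizes, and takes the dominant right singular
vectors as loadings. Two choices deserve emphasis:

* **Scores come from the raw data, not the residuals.** Residual-space
  scores are orthogonal to $X$ by construction, so they can never remove
  the part of a latent confounder that is correlated with $X$ in the
  sample at hand — and with a shared confounder that chance correlation
  shifts *every* $\hat\alpha_i$ by the same amount, which the mixture
  model then misreads as a dense signal. The package therefore identifies
  the subspace from the residuals but computes scores by projecting the
  standardized raw matrix onto those loadings (the device used by
  factor-adjusted regression estimators in the RUV4/CATE family), then
  orthonormalizes them. In the pleiotropy scenario this is the difference
  between a badly inflated false discovery proportion and a controlled
  one; `scripts/acceptance.R` reports both pipelines.
* **Dimension by parallel analysis.** With `k = "auto"` a singular value
  is kept while it exceeds the 95th percentile of the corresponding
  singular values of B = 20 column-permuted (and re-residualized,
  re-standardized) matrices. On pure noise this keeps zero factors about
  93% of the time; `k_max` defaults to 10. The validity of the global
  $\hat U^Y$ rests on each single mediator contributing little outcome
  variance, which the generator respects.

## The synthetic-data generator

`generate_scenario()` reproduces six study designs with known truth:
linear, measured confounder, binary outcome, hidden exposure-mediator
interactions, unmeasured confounding with dense pleiotropy, and composite
alternatives. Latent states are drawn i.i.d. from dense
$(\pi_{00},\pi_{10},\pi_{01},\pi_{11}) = (0.4, 0.2, 0.2, 0.2)$ or sparse
$(0.88, 0.05, 0.05, 0.02)$ proportions; non-null coefficients are
$\alpha_i = 0.05\tau + h_i$, $h_i \sim N(0, 1/n)$ and
$\beta_i = -0.5\tau + g_i$, $g_i \sim N(0, 4/n)$, with exposure
$X \sim \mathrm{Bernoulli}(0.1)$ and unit error variances; $\tau$ indexes
signal strength (grid 0.1–1.9 in the benchmark designs). Where a
distribution is not pinned down by the design, the defaults are: hidden
interaction and pleiotropy coefficients $\sim U(0.3, 0.6)$ over a hidden
set of 20 mediators, logistic intercept 0 (baseline prevalence 0.5), both
error SDs 1. `generate_statistics()` draws $(a_i, b_i)$ directly from the
mixture model — the natural device for studying the estimator itself,
since the generating parameters are exactly what the EM estimates.

Two honest caveats about what these designs exercise. First, the
coefficient scalings place almost all of the identification burden on the
$b$-margin: at $n = 300$ the non-null $a$-shift is about half a sampling
standard deviation even at $\tau = 1.9$, so absolute power is very small
for *any* procedure, including the oracle, and the FDR-control checks are
the informative ones. Second, the designs use independent mediator errors;
real methylation panels are correlated beyond what the latent-factor
scenarios induce, so passing tests here demonstrate calibration under the
stated designs, not under arbitrary dependence.

## Identifiability and known limitations

* When the $a$-margin barely separates, the split of the strong-$b$ mass
  between $\pi_{01}$ and $\pi_{11}$ sits on a nearly flat likelihood
  ridge, and at moderate $m$ the exact MLE can collapse
  $\hat\pi_{01} \to 0$, labelling every strong-$b$ unit a discovery. The
  AIC fold-back removes the degenerate version of this collapse and the
  evaluation suite verifies control at $m = 1000$, but boundary designs
  (very sparse states, weak margins) remain the hardest regime for any
  plug-in lfdr method; asymptotic FDR control does not preclude
  finite-sample excursions there.
* The lfdr is a posterior probability under the fitted mixture; it
  inherits the model's assumptions (conditional independence of the two
  margins, normal alternatives, known unit variances).
* The two-step composite estimator freezes step-one moments; gross
  misfit in step one propagates.
* Survival outcomes, exposure-mediator interactions *inside* the fitted
  model, and robust standard errors are out of scope; interactions appear
  only as a misspecification stress test in the generator.

## Evaluation configuration

The test suite and `scripts/acceptance.R` run the full pipelines at
$n = 300$, $m = 1000$ with 100 replicates for the FDR studies (50 for the
latent-adjustment study, 60 for the global null, 20 seeds at $m = 5000$
for parameter recovery), EM controls `tol = 1e-7`, `n_restarts = 2`.
These sizes give Monte-Carlo standard errors small enough that the
"mean FDP $\le \alpha + 2\,\mathrm{SE}$" checks are meaningful while the
whole suite stays comfortably runnable on a laptop.
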