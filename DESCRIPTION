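Package: mlfdr
Title: Local False Discovery Rate Screening for High-Dimensional Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Large-scale mediation screening under the composite null
    hypothesis alpha*beta = 0. Per-unit structural equation models yield
    scaled coefficient estimates whose joint distribution is modelled as a
    four-component (or larger, composite-alternative) bivariate Gaussian
    mixture with unit-specific known variances; the mixture is estimated by
    an EM algorithm and hypotheses are screened by thresholding the
    composite-null local false discovery rate with an adaptive step-up
    procedure. Includes a two-step EM for composite alternatives with AIC
    model selection, a residual-PCA latent-factor adjustment for unmeasured
    confounding and pleiotropy, and simulation scenarios with FDR/power
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
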