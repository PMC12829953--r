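#' Assemble and validate a mediation dataset
#'
#' Bundles the raw inputs of a large-scale mediation screen: an exposure
#' (shared across units, or unit-specific as in SNP-CpG-gene triplets), an
#' `n x m` mediator matrix, outcomes (one column per unit, or a single
#' outcome shared by all units), and optional measured covariates.
#'
#' @param exposure Numeric vector of length `n`, or an `n x m` matrix when
#'   each unit has its own exposure.
#' @param mediators Numeric `n x m` matrix; one column per testing unit.
#' @param outcomes Numeric `n x m` matrix, or a length-`n` vector shared by
#'   all units. Must contain only 0/1 when `outcome_type = "binary"`.
#' @param covariates Optional numeric `n x q` matrix of measured covariates.
#' @param outcome_type `"continuous"` (linear outcome model) or `"binary"`
#'   (logistic outcome model).
#' @param unit_ids Character labels for the `m` units; defaults to mediator
#'   column names or `unit_1 ... unit_m`.
#'
#' @return An object of class `mediation_dataset`: a list with elements
#'   `exposure`, `mediators`, `outcomes`, `covariates`, `outcome_type`,
#'   `unit_ids`, `n`, `m`.
#' @export
#' @examples
#' set.seed(1)
#' X <- rbinom(50, 1, 0.3)
#' M <- matrix(rnorm(50 * 4), 50, 4)
#' Y <- M * 0.5 + matrix(rnorm(50 * 4), 50, 4)
#' dat <- mediation_dataset(X, M, Y)
#' dat$m
mediation_dataset <- function(exposure, mediators, outcomes,
                              covariates = NULL,
                              outcome_type = c("continuous", "binary"),
                              unit_ids = NULL) {
  outcome_type <- match.arg(outcome_type)
  mediators <- as.matrix(mediators)
  n <- nrow(mediators)
  m <- ncol(mediators)

  if (is.matrix(exposure) && ncol(exposure) > 1L) {
    exposure <- as.matrix(exposure)
    if (!all(dim(exposure) == c(n, m)))
      stop("per-unit exposure matrix must be n x m", call. = FALSE)
  } else {
    exposure <- as.numeric(exposure)
    if (length(exposure) != n)
      stop("exposure length must equal nrow(mediators)", call. = FALSE)
  }

  shared_outcome <- FALSE
  if (is.matrix(outcomes) && ncol(outcomes) > 1L) {
    outcomes <- as.matrix(outcomes)
    if (!all(dim(outcomes) == c(n, m)))
      stop("outcome matrix must be n x m", call. = FALSE)
  } else {
    outcomes <- as.numeric(outcomes)
    if (length(outcomes) != n)
      stop("outcome length must equal nrow(mediators)", call. = FALSE)
    shared_outcome <- TRUE
  }

  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n)
      stop("covariates must have n rows", call. = FALSE)
  }
  q <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n < q + 3L)
    stop("need at least q + 3 samples", call. = FALSE)

  vals <- c(exposure, mediators, outcomes, covariates)
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("missing or non-finite values in input matrices", call. = FALSE)
  if (outcome_type == "binary" && !all(outcomes %in% c(0, 1)))
    stop("binary outcomes must take values in {0, 1}", call. = FALSE)

  if (is.null(unit_ids)) {
    unit_ids <- colnames(mediators)
    if (is.null(unit_ids)) unit_ids <- paste0("unit_", seq_len(m))
  }
  if (length(unit_ids) != m)
    stop("unit_ids must have length m", call. = FALSE)

  structure(
    list(exposure = exposure, mediators = mediators, outcomes = outcomes,
         covariates = covariates, outcome_type = outcome_type,
         unit_ids = as.character(unit_ids), n = n, m = m,
         shared_outcome = shared_outcome),
    class = "mediation_dataset"
  )
}

#' @export
print.mediation_dataset <- function(x, ...) {
  cat("Mediation dataset: n =", x$n, "samples, m =", x$m, "units\n")
  cat("  exposure:", if (is.matrix(x$exposure)) "unit-specific" else "shared",
      "| outcome:", x$outcome_type,
      if (x$shared_outcome) "(shared)" else "(per-unit)", "\n")
  cat("  covariates:", if (is.null(x$covariates)) 0 else ncol(x$covariates), "\n")
  invisible(x)
}

#' Construct a per-unit coefficient summary
#'
#' The sufficient input to all downstream inference: for each unit `i`, the
#' root-n scaled coefficient estimates \eqn{a_i = \sqrt{n}\,\hat\alpha_i},
#' \eqn{b_i = \sqrt{n}\,\hat\beta_i} and their conditional variances
#' \eqn{\sigma_{i1}^2 = n\,\mathrm{Var}(\hat\alpha_i)},
#' \eqn{\sigma_{i2}^2 = n\,\mathrm{Var}(\hat\beta_i)}.
#'
#' @param a,b Numeric vectors of scaled coefficient estimates.
#' @param var1,var2 Positive numeric vectors of scaled variances.
#' @param n Sample size behind the estimates.
#' @param unit_ids Optional character labels.
#' @return A `coef_summary`: a data.frame with columns `unit_id`, `a`, `b`,
#'   `var1`, `var2` and attribute `n`.
#' @export
coef_summary <- function(a, b, var1, var2, n, unit_ids = NULL) {
  m <- length(a)
  stopifnot(length(b) == m, length(var1) == m, length(var2) == m)
  if (any(var1 <= 0) || any(var2 <= 0))
    stop("variances must be strictly positive", call. = FALSE)
  if (anyNA(c(a, b, var1, var2)) || any(!is.finite(c(a, b, var1, var2))))
    stop("non-finite values in coefficient summary", call. = FALSE)
  if (is.null(unit_ids)) unit_ids <- paste0("unit_", seq_len(m))
  out <- data.frame(unit_id = as.character(unit_ids),
                    a = as.numeric(a), b = as.numeric(b),
                    var1 = as.numeric(var1), var2 = as.numeric(var2),
                    stringsAsFactors = FALSE)
  attr(out, "n") <- as.integer(n)
  class(out) <- c("coef_summary", "data.frame")
  out
}

#' @export
print.coef_summary <- function(x, ...) {
  cat("Coefficient summary for", nrow(x), "units (n =", attr(x, "n"), "samples)\n")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

summary_table_cols <- c("unit_id", "alpha_hat", "beta_hat",
                        "se_alpha", "se_beta", "n")

#' Build a coefficient summary from precomputed regression output
#'
#' Converts a table of raw per-unit estimates \eqn{\hat\alpha_i,
#' \hat\beta_i} and standard errors (as produced by an external regression
#' workflow) to the root-n scale used by the mixture model.
#'
#' @param table A data.frame, or path to a delimited file (TSV, or CSV when
#'   the name ends in `.csv`), with columns `unit_id`, `alpha_hat`,
#'   `beta_hat`, `se_alpha`, `se_beta`, `n`.
#' @return A [coef_summary()].
#' @export
summary_from_table <- function(table) {
  if (is.character(table)) table <- read_delim_matrix(table, rownames = FALSE)
  table <- as.data.frame(table)
  missing_cols <- setdiff(summary_table_cols, names(table))
  if (length(missing_cols))
    stop("summary table is missing columns: ",
         paste(missing_cols, collapse = ", "),
         " (expected header: ", paste(summary_table_cols, collapse = ", "), ")",
         call. = FALSE)
  if (any(table$se_alpha <= 0) || any(table$se_beta <= 0))
    stop("standard errors must be strictly positive", call. = FALSE)
  n <- unique(table$n)
  if (length(n) != 1L)
    stop("all rows must share one sample size n", call. = FALSE)
  coef_summary(a = sqrt(n) * table$alpha_hat,
               b = sqrt(n) * table$beta_hat,
               var1 = n * table$se_alpha^2,
               var2 = n * table$se_beta^2,
               n = n, unit_ids = table$unit_id)
}

#' Write a coefficient summary as a delimited table
#'
#' Writes the raw-scale schema (`unit_id`, `alpha_hat`, `beta_hat`,
#' `se_alpha`, `se_beta`, `n`) so that [summary_from_table()] round-trips.
#'
#' @param summary A [coef_summary()].
#' @param path Output file path (TSV).
#' @export
write_summary <- function(summary, path) {
  n <- attr(summary, "n")
  tab <- data.frame(unit_id = summary$unit_id,
                    alpha_hat = summary$a / sqrt(n),
                    beta_hat = summary$b / sqrt(n),
                    se_alpha = sqrt(summary$var1 / n),
                    se_beta = sqrt(summary$var2 / n),
                    n = n)
  write_delim_atomic(format(tab, digits = 17, scientific = FALSE,
                            trim = TRUE), path)
  invisible(path)
}

# Delimited matrix reader: TSV by default, comma accepted for .csv; first
# row header, optionally first column sample IDs.
read_delim_matrix <- function(path, rownames = TRUE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!rownames) return(df)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- as.character(df[[1]])
  storage.mode(mat) <- "double"
  mat
}

write_delim_atomic <- function(df, path, sample_ids = NULL) {
  if (!is.null(sample_ids)) df <- cbind(sample_id = sample_ids, df)
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
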