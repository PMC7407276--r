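#' Imputation error between masked truths and imputed values
#'
#' Two variants are provided. `"as_printed"` follows the commonly printed
#' per-entry formula `sum(sqrt((x - x')^2)) / n`, which is algebraically
#' the mean absolute error; it is the default so results are comparable
#' with published tables using that formula. `"quadratic"` is the
#' conventional root-mean-square error `sqrt(mean((x - x')^2))`. By
#' Jensen's inequality `as_printed <= quadratic` always.
#'
#' @param truth numeric vector of ground-truth masked values.
#' @param imputed numeric vector of imputed values, same length.
#' @param variant `"as_printed"` (mean absolute error; default) or
#'   `"quadratic"` (root mean squared error).
#' @return A single non-negative number.
#' @export
imputation_error <- function(truth, imputed,
                             variant = c("as_printed", "quadratic")) {
  variant <- match.arg(variant)
  if (length(truth) == 0) stop("no masked entries to score")
  if (length(truth) != length(imputed))
    stop("truth and imputed must have equal length")
  d <- truth - imputed
  switch(variant,
         as_printed = mean(abs(d)),
         quadratic = sqrt(mean(d * d)))
}

#' Score an imputation result against its masking trial
#'
#' Convenience wrapper extracting the completed values at the trial's
#' masked index and calling [imputation_error()].
#'
#' @param trial a `masked_trial`.
#' @param result an `imputation_result` for `trial$corrupted`.
#' @param variant see [imputation_error()].
#' @return A single non-negative number.
#' @export
trial_error <- function(trial, result, variant = "as_printed") {
  imputation_error(trial$truth, imputed_at(result, trial), variant = variant)
}

#' Spearman correlation of each feature with an ordinal grade
#'
#' Rank correlation (average ranks for ties) between every feature column
#' and the tumour-grade variable treated as ordinal. Constant features
#' get correlation 0 with a warning.
#'
#' @param completed an [omics_matrix()] (fully observed) or numeric
#'   matrix.
#' @param grade ordinal vector, one value per sample.
#' @return Named numeric vector, one correlation per feature, in
#'   \[-1, 1\].
#' @export
spearman_vs_grade <- function(completed, grade) {
  x <- if (is_omics_matrix(completed)) completed$values else as.matrix(completed)
  if (length(grade) != nrow(x))
    stop("grade must have one value per sample")
  sds <- apply(x, 2, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const))
    warning(sprintf("%d constant feature(s); correlation set to 0", sum(const)))
  rho <- suppressWarnings(
    as.vector(stats::cor(x, grade, method = "spearman")))
  rho[const] <- 0
  names(rho) <- colnames(x)
  rho
}

#' Univariate Cox proportional-hazards coefficient
#'
#' Fits a single-covariate Cox model (Breslow ties) and returns the
#' estimated log-hazard-ratio. Non-converged fits (monotone likelihood /
#' separation) are capped at `cap` with a warning.
#'
#' @param feature numeric covariate vector.
#' @param time positive survival/censoring times.
#' @param event logical (or 0/1) event indicators; at least one event
#'   required.
#' @param cap absolute bound applied to non-converged coefficients
#'   (default 20).
#' @return The coefficient (scalar).
#' @export
cox_univariate <- function(feature, time, event, cap = 20) {
  event <- as.logical(event)
  if (!any(event)) stop("at least one event is required")
  if (stats::sd(feature) == 0) return(0)
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ feature, ties = "breslow"),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  b <- unname(stats::coef(fit)[1])
  if (!is.finite(b)) b <- 0
  if (flagged && abs(b) > cap) {
    warning("possible separation; coefficient capped")
    b <- sign(b) * cap
  }
  b
}

#' Univariate Cox coefficients for every feature
#'
#' @param completed an [omics_matrix()] or numeric matrix.
#' @param time,event as in [cox_univariate()].
#' @return Named numeric vector of per-feature coefficients.
#' @export
cox_coefficients <- function(completed, time, event) {
  x <- if (is_omics_matrix(completed)) completed$values else as.matrix(completed)
  out <- vapply(seq_len(ncol(x)), function(j)
    suppressWarnings(cox_univariate(x[, j], time, event)), numeric(1))
  names(out) <- colnames(x)
  out
}

#' Concordance index between two coefficient vectors
#'
#' Fraction of feature pairs whose ordering by the imputed-data
#' coefficients agrees with the ordering by the ground-truth
#' coefficients; tied pairs (in either vector) contribute 0.5. A value of
#' 1 means identical rankings, 0.5 chance agreement, 0 full reversal.
#'
#' @param coef_truth,coef_imputed numeric vectors of equal length >= 2.
#' @return A number in \[0, 1\].
#' @export
concordance_of_coefficients <- function(coef_truth, coef_imputed) {
  n <- length(coef_truth)
  if (n < 2 || length(coef_imputed) != n)
    stop("two equal-length vectors of length >= 2 are required")
  st <- sign(outer(coef_truth, coef_truth, "-"))
  si <- sign(outer(coef_imputed, coef_imputed, "-"))
  up <- upper.tri(st)
  agree <- st[up] * si[up]
  (sum(agree > 0) + 0.5 * sum(agree == 0)) / length(agree)
}

#' Compare two methods' per-trial errors with a Wilcoxon test
#'
#' Two-sided Wilcoxon test on matched trials: the paired signed-rank test
#' by default (methods are scored on identical masks), falling back to
#' the rank-sum test with `paired = FALSE`. The exact distribution is
#' used for small samples without ties. Identical inputs yield p = 1
#' with a warning.
#'
#' @param errors_a,errors_b numeric vectors of per-trial errors.
#' @param paired use the signed-rank test on trial-wise differences
#'   (default `TRUE`).
#' @return The two-sided p-value.
#' @export
compare_methods <- function(errors_a, errors_b, paired = TRUE) {
  if (paired && length(errors_a) != length(errors_b))
    stop("paired comparison requires equal-length error vectors")
  if (paired && all(errors_a == errors_b)) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  if (!paired && length(unique(c(errors_a, errors_b))) == 1) {
    warning("all values identical; p = 1")
    return(1)
  }
  suppressWarnings(
    stats::wilcox.test(errors_a, errors_b, paired = paired,
                       alternative = "two.sided")$p.value)
}

#' Variance of pairwise coefficient differences
#'
#' Sample variance of `coef_method - coef_truth`; a small spread around
#' zero indicates the imputed-data coefficients track the ground-truth
#' ones closely. Invariant to a constant offset.
#'
#' @param coef_truth,coef_method numeric vectors of equal length.
#' @return The variance (scalar).
#' @export
coefficient_difference_spread <- function(coef_truth, coef_method) {
  if (length(coef_truth) != length(coef_method))
    stop("vectors must have equal length")
  stats::var(coef_method - coef_truth)
}

#' Summarise per-trial errors into an evaluation report
#'
#' Computes per-method mean error with a normal-approximation 95%
#' confidence interval (`mean +/- 1.96 * SE` over trials) and pairwise
#' Wilcoxon signed-rank p-values across methods.
#'
#' @param errors named list: one numeric vector of per-trial errors per
#'   method (equal lengths, same trial order).
#' @param variant label of the error variant used (stored, not checked).
#' @return An `eval_report`: list with `summary` (data.frame: method,
#'   mean, ci_lo, ci_hi, n_trials), `pairwise_p` (matrix), `variant`.
#' @export
eval_report <- function(errors, variant = "as_printed") {
  stopifnot(is.list(errors), length(errors) >= 1, !is.null(names(errors)))
  summary_df <- do.call(rbind, lapply(names(errors), function(nm) {
    e <- errors[[nm]]
    se <- stats::sd(e) / sqrt(length(e))
    data.frame(method = nm, mean = mean(e),
               ci_lo = mean(e) - 1.96 * se, ci_hi = mean(e) + 1.96 * se,
               n_trials = length(e))
  }))
  methods <- names(errors)
  pw <- matrix(NA_real_, length(methods), length(methods),
               dimnames = list(methods, methods))
  if (length(methods) > 1) {
    for (a in seq_along(methods)) for (b in seq_along(methods)) {
      if (a < b) {
        pw[a, b] <- pw[b, a] <-
          suppressWarnings(compare_methods(errors[[a]], errors[[b]]))
      }
    }
  }
  structure(list(summary = summary_df, pairwise_p = pw,
                 per_trial = errors, variant = variant),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report (%s error, %d trials)\n", x$variant,
              x$summary$n_trials[1]))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
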