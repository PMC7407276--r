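#' Log-transform an expression matrix
#'
#' Replaces every observed entry by `log(value + pseudocount)`. Intended
#' for non-negative normalised expression units (e.g. RPKM) ahead of
#' z-scoring; missing entries and the mask are untouched.
#'
#' @param m an [omics_matrix()] with `modality = "expression"`.
#' @param pseudocount non-negative offset added before the (natural) log;
#'   default 1 so zero counts map to zero.
#' @return The transformed `omics_matrix`.
#' @export
log_transform <- function(m, pseudocount = 1) {
  stopifnot(is_omics_matrix(m))
  if (m$modality != "expression")
    stop("log_transform applies to expression matrices only")
  obs <- m$mask & !is.na(m$values)
  bad <- which(obs & m$values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative observed value in feature '%s'",
                 m$feature_ids[bad[1, 2]]))
  v <- m$values
  v[obs] <- log(v[obs] + pseudocount)
  replace_values(m, v, mask = m$mask)
}

#' Negative-log-transform a methylation matrix
#'
#' Replaces every observed entry by `-log(value + epsilon)`. Methylation
#' levels live in \[0, 1\]; `epsilon` guards `log(0)` for fully
#' unmethylated sites.
#'
#' @param m an [omics_matrix()] with `modality = "methylation"`.
#' @param epsilon small positive offset, default `1e-6`.
#' @return The transformed `omics_matrix`.
#' @export
neglog_transform <- function(m, epsilon = 1e-6) {
  stopifnot(is_omics_matrix(m))
  if (m$modality != "methylation")
    stop("neglog_transform applies to methylation matrices only")
  obs <- m$mask & !is.na(m$values)
  bad <- which(obs & (m$values < 0 | m$values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("methylation value outside [0, 1] in feature '%s'",
                 m$feature_ids[bad[1, 2]]))
  v <- m$values
  v[obs] <- -log(v[obs] + epsilon)
  replace_values(m, v, mask = m$mask)
}

#' Drop features containing any missing value
#'
#' Mirrors the pre-processing step that removes incompletely observed
#' genes so the remaining matrix provides a ground truth for masking
#' experiments. Feature order is preserved.
#'
#' @param m an [omics_matrix()].
#' @return An `omics_matrix` restricted to fully observed features.
#' @export
drop_na_features <- function(m) {
  stopifnot(is_omics_matrix(m))
  keep <- colSums(!m$mask) == 0
  if (!any(keep)) stop("every feature contains missing values; nothing left")
  m[, keep]
}

#' Fit per-feature z-scoring statistics on training data
#'
#' Computes each feature's mean and sample standard deviation (ddof = 1)
#' over its observed entries only. Constant features get `sd = 1` (with a
#' warning) so scaling never divides by zero.
#'
#' @param train an [omics_matrix()]; every feature needs at least two
#'   observed entries.
#' @return An object of class `scaler_stats`: list with numeric vectors
#'   `mean` and `sd` (both length `n_features`) and `feature_ids`.
#' @export
fit_scaler <- function(train) {
  stopifnot(is_omics_matrix(train))
  n_obs <- colSums(train$mask)
  if (any(n_obs < 2))
    stop(sprintf("feature '%s' has fewer than 2 observed entries",
                 train$feature_ids[which(n_obs < 2)[1]]))
  mu <- colMeans(train$values, na.rm = TRUE)
  sd_ <- apply(train$values, 2, stats::sd, na.rm = TRUE)
  degenerate <- sd_ == 0 | !is.finite(sd_)
  if (any(degenerate)) {
    warning(sprintf("%d constant feature(s); sd set to 1", sum(degenerate)))
    sd_[degenerate] <- 1
  }
  structure(list(mean = unname(mu), sd = unname(sd_),
                 feature_ids = train$feature_ids),
            class = "scaler_stats")
}

#' @export
print.scaler_stats <- function(x, ...) {
  cat(sprintf("scaler_stats for %d features (mean of means %.3g, mean of sds %.3g)\n",
              length(x$mean), mean(x$mean), mean(x$sd)))
  invisible(x)
}

check_scaler_dims <- function(m, s) {
  if (length(s$mean) != ncol(m$values))
    stop(sprintf("scaler has %d features but matrix has %d",
                 length(s$mean), ncol(m$values)))
}

#' Apply or invert per-feature z-scoring
#'
#' `apply_scaler` maps observed entries to `(x - mean) / sd` using the
#' *training* statistics in `s`; `invert_scaler` undoes it. Applying a
#' train-fitted scaler to validation or test data deliberately reuses the
#' training statistics — test statistics are never recomputed.
#'
#' @param m an [omics_matrix()].
#' @param s a `scaler_stats` object from [fit_scaler()].
#' @return The (inverse-)scaled `omics_matrix`.
#' @export
apply_scaler <- function(m, s) {
  stopifnot(is_omics_matrix(m), inherits(s, "scaler_stats"))
  check_scaler_dims(m, s)
  v <- sweep(sweep(m$values, 2, s$mean, "-"), 2, s$sd, "/")
  replace_values(m, v, mask = m$mask)
}

#' @rdname apply_scaler
#' @export
invert_scaler <- function(m, s) {
  stopifnot(is_omics_matrix(m), inherits(s, "scaler_stats"))
  check_scaler_dims(m, s)
  v <- sweep(sweep(m$values, 2, s$sd, "*"), 2, s$mean, "+")
  replace_values(m, v, mask = m$mask)
}

#' Split samples into train / validation / test sets
#'
#' Deterministic, optionally stratified sampling of disjoint index sets.
#' With stratification, each stratum is split at the requested fractions
#' so per-stratum proportions stay within one sample of the global
#' fractions.
#'
#' @param m an [omics_matrix()] (or anything with a known sample count via
#'   `n_samples`).
#' @param fractions numeric vector summing to 1; length 2 (`train`,
#'   `test`) or 3 (`train`, `val`, `test`).
#' @param stratify optional categorical vector, one label per sample.
#' @param seed integer seed; the split is a pure function of it.
#' @param n_samples sample count override when `m` is missing.
#' @return A `split_spec` list with integer vectors `train_idx`,
#'   `val_idx`, `test_idx` (val empty for 2-way splits) and the `seed`.
#' @examples
#' g <- generate_matrix(n_samples = 50, n_features = 10, latent_rank = 2, seed = 1)
#' sp <- split_samples(g$matrix, fractions = c(0.8, 0.2), seed = 7)
#' lengths(sp[c("train_idx", "val_idx", "test_idx")])
#' @export
split_samples <- function(m, fractions = c(0.8, 0.2), stratify = NULL,
                          seed = 1, n_samples = NULL) {
  if (is.null(n_samples)) {
    stopifnot(is_omics_matrix(m))
    n_samples <- nrow(m$values)
  }
  if (abs(sum(fractions) - 1) > 1e-8) stop("`fractions` must sum to 1")
  if (!length(fractions) %in% c(2, 3)) stop("2 or 3 fractions expected")
  if (is.null(stratify)) stratify <- rep("all", n_samples)
  if (length(stratify) != n_samples)
    stop("`stratify` must have one label per sample")

  k <- length(fractions)
  parts <- vector("list", k)
  levs <- unique(stratify)
  perms <- with_seed(seed, lapply(levs, function(lev) {
    sample.int(sum(stratify == lev))
  }))
  for (li in seq_along(levs)) {
    idx <- which(stratify == levs[li])
    if (length(idx) < k)
      stop(sprintf("stratum '%s' has fewer samples (%d) than splits (%d)",
                   levs[li], length(idx), k))
    idx <- idx[perms[[li]]]
    # largest-remainder apportionment keeps each stratum within 1 sample
    # of the global fractions
    counts <- floor(fractions * length(idx))
    rem <- length(idx) - sum(counts)
    if (rem > 0) {
      order_rem <- order(fractions * length(idx) - counts, decreasing = TRUE)
      counts[order_rem[seq_len(rem)]] <- counts[order_rem[seq_len(rem)]] + 1
    }
    at <- 0
    for (p in seq_len(k)) {
      parts[[p]] <- c(parts[[p]], idx[seq_len(counts[p]) + at])
      at <- at + counts[p]
    }
  }
  parts <- lapply(parts, sort)
  if (k == 2) parts <- list(parts[[1]], integer(0), parts[[2]])
  structure(list(train_idx = parts[[1]], val_idx = parts[[2]],
                 test_idx = parts[[3]], seed = seed),
            class = "split_spec")
}
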