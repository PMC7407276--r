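# Every imputer returns an "imputation_result" with a fully observed
# completed matrix in which all originally observed entries are
# bit-identical to the input.

new_imputation_result <- function(corrupted, fill, method,
                                  iterations_run = 1L,
                                  per_iteration_delta = numeric(0),
                                  converged = TRUE) {
  v <- corrupted$values
  miss <- !corrupted$mask
  stopifnot(length(fill) == sum(miss))
  v[miss] <- fill
  structure(list(
    completed = replace_values(corrupted, v,
                               mask = matrix(TRUE, nrow(v), ncol(v))),
    method = method, iterations_run = as.integer(iterations_run),
    per_iteration_delta = per_iteration_delta, converged = converged),
    class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("imputation_result (%s): %d x %d completed matrix, %d iteration(s)\n",
              x$method, nrow(x$completed$values), ncol(x$completed$values),
              x$iterations_run))
  invisible(x)
}

# values of the completed matrix at a trial's masked index
imputed_at <- function(result, trial) {
  result$completed$values[trial$masked_index]
}

#' Impute missing values with a fitted VAE by iterative reconstruction
#'
#' The corrupted matrix is scaled with the model's *training* statistics;
#' missing entries are initialised with standard-normal draws; then for
#' each iteration the filled matrix is encoded, the posterior mean is
#' decoded, and missing entries are replaced by the decoder mean while
#' observed entries are left untouched. After the final iteration the
#' matrix is inverse-scaled. Convergence is fast in practice — the
#' imputed values are mostly stable after two or three passes, hence the
#' default of three.
#'
#' The decoder *mean* is always used as the fill value; under shift
#' correction (`shift_lambda > 0`) that mean models the low-shifted
#' missing-data distribution while observed data were modelled as
#' `N(mu + lambda*sigma, sigma)` during training.
#'
#' @param model a fitted [vae()].
#' @param corrupted an [omics_matrix()] on the raw data scale, with
#'   missing entries.
#' @param n_iterations number of encode–decode refinement passes
#'   (default 3).
#' @param seed seed for the initial standard-normal fill.
#' @return An `imputation_result`; `per_iteration_delta` holds the mean
#'   absolute change of the imputed entries (scaled space) at each
#'   iteration.
#' @export
impute_vae <- function(model, corrupted, n_iterations = 3, seed = 1) {
  stopifnot(inherits(model, "vae"), n_iterations >= 1)
  m <- as_omics(corrupted)
  if (ncol(m$values) != model$config$input_dim)
    stop(sprintf("matrix has %d features but model expects %d",
                 ncol(m$values), model$config$input_dim))
  miss <- !m$mask
  if (!any(miss)) {
    return(new_imputation_result(m, numeric(0), "vae",
                                 iterations_run = 0L))
  }
  xs <- apply_scaler(m, model$scaler)$values
  fill <- with_seed(seed, stats::rnorm(sum(miss)))
  xs[miss] <- fill
  deltas <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    enc <- encode(model, xs)
    dec <- decode(model, enc$mu)
    new_fill <- dec$mu[miss]
    deltas[it] <- mean(abs(new_fill - xs[miss]))
    xs[miss] <- new_fill
  }
  raw_fill <- xs[miss] * rep(model$scaler$sd, each = nrow(xs))[miss] +
    rep(model$scaler$mean, each = nrow(xs))[miss]
  new_imputation_result(m, raw_fill, "vae",
                        iterations_run = n_iterations,
                        per_iteration_delta = deltas)
}

#' Select the shift-correction parameter on validation data
#'
#' Simulates the lowest-value missingness scenario on the validation set
#' (lowest `quantile` of values eligible, `within_rate` of them masked),
#' retrains the VAE once per candidate `lambda`, and returns the grid
#' value with the smallest validation imputation error (ties broken
#' towards the smaller `lambda`). The selected value is intended to be
#' reused across low-value-missing severities without re-selection.
#'
#' @param train an [omics_matrix()], fully observed training data.
#' @param val an [omics_matrix()], fully observed validation data.
#' @param lambda_grid candidate shift multipliers (default
#'   `c(0, 0.2, 0.4, 0.6, 0.8, 1, 1.5, 2)`).
#' @param vae_args list of arguments passed on to [vae()] (architecture,
#'   epochs, learning rate, ...).
#' @param quantile,within_rate the validation masking scenario
#'   (defaults: lowest 10%, half masked).
#' @param seed seed for the validation mask and imputation fills.
#' @param error_variant see [imputation_error()].
#' @return The selected `lambda` (scalar), with the per-`lambda`
#'   validation errors attached as attribute `"errors"`.
#' @export
select_shift_lambda <- function(train, val,
                                lambda_grid = c(0, 0.2, 0.4, 0.6, 0.8, 1, 1.5, 2),
                                vae_args = list(),
                                quantile = 0.10, within_rate = 0.50,
                                seed = 1, error_variant = "as_printed") {
  if (length(lambda_grid) == 0) stop("lambda_grid must be non-empty")
  lambda_grid <- sort(lambda_grid)
  train <- as_omics(train)
  val <- as_omics(val)
  trial <- mask_lowest_values(val, quantile = quantile,
                              within_rate = within_rate, seed = seed)
  errors <- vapply(lambda_grid, function(lam) {
    fit <- do.call(vae, c(list(x = train, shift_lambda = lam), vae_args))
    res <- impute_vae(fit, trial$corrupted, seed = seed)
    imputation_error(trial$truth, imputed_at(res, trial),
                     variant = error_variant)
  }, numeric(1))
  names(errors) <- lambda_grid
  best <- lambda_grid[which.min(errors)]
  attr(best, "errors") <- errors
  best
}

#' Weighted K-nearest-neighbour imputation
#'
#' For each missing entry, candidate samples are those in the pool
#' (training samples plus the corrupted samples themselves) that have the
#' target feature observed. Distances are Euclidean over the features
#' observed in both samples, normalised by the shared-feature count so
#' rows with different missing patterns are comparable. The `k` nearest
#' candidates contribute a `1/distance`-weighted average; any
#' zero-distance candidates are averaged unweighted instead. With fewer
#' than `k` candidates all are used (with a warning); with none, the
#' training feature mean is used (with a warning).
#'
#' @param train an [omics_matrix()] of complete reference samples.
#' @param corrupted an [omics_matrix()] with missing entries.
#' @param k number of neighbours (default 10).
#' @param pool `"both"` (default) searches training and test samples;
#'   `"train"` restricts candidates to the training set.
#' @return An `imputation_result`.
#' @export
impute_knn <- function(train, corrupted, k = 10, pool = c("both", "train")) {
  pool <- match.arg(pool)
  stopifnot(k >= 1)
  train <- as_omics(train)
  m <- as_omics(corrupted)
  if (ncol(train$values) != ncol(m$values))
    stop("train and corrupted matrices must share the feature set")
  miss <- which(!m$mask, arr.ind = TRUE)
  if (nrow(miss) == 0)
    return(new_imputation_result(m, numeric(0), "knn", iterations_run = 0L))

  pv <- if (pool == "both") rbind(train$values, m$values) else train$values
  pmask <- if (pool == "both") rbind(train$mask, m$mask) else train$mask
  self_offset <- if (pool == "both") nrow(train$values) else NA_integer_

  # mean squared difference over shared observed features, via masked
  # cross-products (NA -> 0)
  A <- m$values; A[!m$mask] <- 0
  B <- pv; B[!pmask] <- 0
  Ma <- m$mask * 1; Mb <- pmask * 1
  shared <- Ma %*% t(Mb)
  ss <- (A * A) %*% t(Mb) + Ma %*% t(B * B) - 2 * A %*% t(B)
  D <- sqrt(pmax(ss, 0) / pmax(shared, 1))
  D[shared == 0] <- Inf
  if (pool == "both") {
    D[cbind(seq_len(nrow(m$values)), self_offset + seq_len(nrow(m$values)))] <- Inf
  }

  col_mean <- colMeans(train$values, na.rm = TRUE)
  cand_by_feature <- apply(pmask, 2, which, simplify = FALSE)
  short <- 0L; none <- 0L
  fill_mat <- matrix(NA_real_, nrow(m$values), ncol(m$values))
  for (r in seq_len(nrow(miss))) {
    i <- miss[r, 1]; j <- miss[r, 2]
    cand <- cand_by_feature[[j]]
    d <- D[i, cand]
    ok <- is.finite(d)
    cand <- cand[ok]; d <- d[ok]
    if (length(cand) == 0) {
      none <- none + 1L
      fill_mat[i, j] <- col_mean[j]
      next
    }
    if (length(cand) < k) short <- short + 1L
    use <- order(d)[seq_len(min(k, length(cand)))]
    d_use <- d[use]
    vals <- pv[cand[use], j]
    fill_mat[i, j] <- if (any(d_use == 0)) {
      mean(vals[d_use == 0])
    } else {
      sum(vals / d_use) / sum(1 / d_use)
    }
  }
  if (short > 0)
    warning(sprintf("%d entr%s had fewer than k candidates; used all available",
                    short, if (short == 1) "y" else "ies"))
  if (none > 0)
    warning(sprintf("%d entr%s had no candidate; filled with the feature mean",
                    none, if (none == 1) "y" else "ies"))
  new_imputation_result(m, fill_mat[!m$mask], "knn")
}

#' Iterative SVD (eigengene-regression) imputation
#'
#' Classic iterative SVD completion: missing entries are initialised with
#' feature means; each iteration takes the top-`rank` right singular
#' vectors (eigengenes in feature space) of the *complete* rows of the
#' combined (reference + corrupted) matrix, regresses each incomplete
#' sample's observed coordinates on the eigengenes restricted to those
#' positions, and refills its missing coordinates from the regression
#' reconstruction. Iteration stops when the total absolute change drops
#' below `tol`.
#'
#' The eigengene basis deliberately excludes incomplete rows: if a filled
#' row takes part in a full-rank decomposition it lies exactly in the
#' span of the eigengenes, the regression reproduces its own fill, and
#' the procedure degenerates into mean imputation. Restricting the basis
#' to complete rows keeps the full-rank setting a genuine predictor (this
#' is also why the classical method must re-estimate the decomposition
#' for samples it has not seen). When no complete row exists, all rows
#' (with current fills) are used and the iteration refines the basis and
#' the fills jointly.
#'
#' @param reference an [omics_matrix()] of complete samples (may be
#'   `NULL` to complete `corrupted` on its own).
#' @param corrupted an [omics_matrix()] with missing entries.
#' @param rank number of eigengenes; `NULL` (default) = full rank of the
#'   basis rows, `min(n_basis, n_features)`.
#' @param tol convergence threshold on total absolute change; default
#'   `1e-4` times the Frobenius norm of the initial filled matrix.
#' @param max_iter iteration cap (default 100); hitting it flags
#'   `converged = FALSE` with a warning.
#' @return An `imputation_result`; `per_iteration_delta` records the
#'   total absolute change per iteration.
#' @export
impute_svd <- function(reference, corrupted, rank = NULL, tol = NULL,
                       max_iter = 100) {
  m <- as_omics(corrupted)
  miss <- !m$mask
  if (!any(miss))
    return(new_imputation_result(m, numeric(0), "svd", iterations_run = 0L))
  if (!is.null(reference)) {
    reference <- as_omics(reference)
    if (ncol(reference$values) != ncol(m$values))
      stop("reference and corrupted matrices must share the feature set")
    X <- rbind(reference$values, m$values)
    obs_mask <- rbind(reference$mask, m$mask)
    offset <- nrow(reference$values)
  } else {
    X <- m$values
    obs_mask <- m$mask
    offset <- 0L
  }
  n <- nrow(X); p <- ncol(X)
  col_mean <- colMeans(X, na.rm = TRUE)
  col_mean[is.nan(col_mean)] <- 0
  miss_all <- !obs_mask
  X[miss_all] <- rep(col_mean, each = n)[miss_all]
  if (is.null(tol)) tol <- 1e-4 * sqrt(sum(X^2))

  incomplete <- which(rowSums(miss_all) > 0)
  basis_rows <- which(rowSums(miss_all) == 0)
  if (length(basis_rows) == 0) basis_rows <- seq_len(n)
  L <- if (is.null(rank)) min(length(basis_rows), p) else rank
  if (L > min(length(basis_rows), p))
    stop("rank exceeds the dimensions of the eigengene basis")

  deltas <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    V <- svd(X[basis_rows, , drop = FALSE], nu = 0, nv = L)$v
    change <- 0
    for (i in incomplete) {
      obs <- obs_mask[i, ]
      Vo <- V[obs, , drop = FALSE]
      G <- crossprod(Vo)
      # tiny ridge keeps the normal equations solvable when the observed
      # rows leave the basis rank-deficient (e.g. full-rank L)
      diag(G) <- diag(G) + 1e-10 * (mean(diag(G)) + 1e-12)
      beta <- solve(G, crossprod(Vo, X[i, obs]))
      recon <- as.vector(V %*% beta)
      mi <- which(miss_all[i, ])
      change <- change + sum(abs(recon[mi] - X[i, mi]))
      X[i, mi] <- recon[mi]
    }
    deltas <- c(deltas, change)
    if (change < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("SVD imputation did not converge in %d iterations", max_iter))
  Xc <- X[offset + seq_len(nrow(m$values)), , drop = FALSE]
  new_imputation_result(m, Xc[miss], "svd",
                        iterations_run = length(deltas),
                        per_iteration_delta = deltas,
                        converged = converged)
}

#' Feature-mean imputation
#'
#' Fills each missing entry with the mean of its feature over the
#' non-missing *training* samples — the baseline every structure-aware
#' method has to beat.
#'
#' @param train an [omics_matrix()] of reference samples.
#' @param corrupted an [omics_matrix()] with missing entries.
#' @return An `imputation_result`.
#' @export
impute_mean <- function(train, corrupted) {
  train <- as_omics(train)
  m <- as_omics(corrupted)
  if (ncol(train$values) != ncol(m$values))
    stop("train and corrupted matrices must share the feature set")
  miss <- !m$mask
  mu <- colMeans(train$values, na.rm = TRUE)
  fill <- rep(mu, each = nrow(m$values))[miss]
  new_imputation_result(m, fill, "mean")
}

#' Random-draw imputation
#'
#' Fills each missing entry with an independent draw from
#' `N(train mean, train sd)` of its feature — the structure-free sampling
#' baseline used in the clinical-concordance comparisons.
#'
#' @param train an [omics_matrix()] of reference samples.
#' @param corrupted an [omics_matrix()] with missing entries.
#' @param seed integer seed.
#' @return An `imputation_result`.
#' @export
impute_random <- function(train, corrupted, seed = 1) {
  train <- as_omics(train)
  m <- as_omics(corrupted)
  if (ncol(train$values) != ncol(m$values))
    stop("train and corrupted matrices must share the feature set")
  miss <- !m$mask
  s <- fit_scaler(train)
  n <- nrow(m$values)
  mu <- rep(s$mean, each = n)[miss]
  sd_ <- rep(s$sd, each = n)[miss]
  fill <- with_seed(seed, stats::rnorm(sum(miss), mean = mu, sd = sd_))
  new_imputation_result(m, fill, "random")
}
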