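# All masking mechanisms return a "masked_trial": the corrupted matrix,
# the ground-truth values removed, and the (sample, feature) index of
# every newly masked entry. Entries already missing in the input are
# never selected, so corrupted + truth always reconstructs the input.

new_masked_trial <- function(m, idx, mechanism, seed) {
  idx <- matrix(as.integer(idx), ncol = 2,
                dimnames = list(NULL, c("sample", "feature")))
  # canonical order: by feature then sample, for reproducible truth files
  ord <- order(idx[, 2], idx[, 1])
  idx <- idx[ord, , drop = FALSE]
  stopifnot(all(m$mask[idx]))
  truth <- m$values[idx]
  v <- m$values
  mk <- m$mask
  v[idx] <- NA_real_
  mk[idx] <- FALSE
  structure(list(corrupted = replace_values(m, v, mask = mk),
                 truth = truth, masked_index = idx,
                 mechanism = mechanism, seed = seed),
            class = "masked_trial")
}

#' @export
print.masked_trial <- function(x, ...) {
  cat(sprintf("masked_trial (%s): %d entries masked of %d x %d matrix\n",
              x$mechanism, nrow(x$masked_index),
              nrow(x$corrupted$values), ncol(x$corrupted$values)))
  invisible(x)
}

#' Mask entries completely at random (MCAR)
#'
#' Masks exactly `round(rate * n_features)` observed entries in every
#' sample row, chosen uniformly without replacement — the per-row variant
#' of completely-random missingness, which pins the global missing rate
#' exactly.
#'
#' @param m an [omics_matrix()].
#' @param rate fraction of each row to mask, in (0, 1).
#' @param seed integer seed.
#' @return A `masked_trial` (see [reconstruct_from_trial()]).
#' @export
mask_mcar <- function(m, rate, seed = 1) {
  stopifnot(is_omics_matrix(m))
  p <- ncol(m$values)
  k <- round(rate * p)
  if (k < 1) stop("rate * n_features rounds to zero entries per row")
  rows <- with_seed(seed, lapply(seq_len(nrow(m$values)), function(i) {
    obs <- which(m$mask[i, ])
    if (length(obs) < k)
      stop(sprintf("sample %d has only %d observed entries (< %d)",
                   i, length(obs), k))
    cbind(i, sort(obs[sample.int(length(obs), k)]))
  }))
  new_masked_trial(m, do.call(rbind, rows), "mcar", seed)
}

#' Mask values within high-GC-content features
#'
#' Selects the `top_frac` fraction of features with the highest GC
#' content (ties broken by ascending feature index) and masks a fixed
#' `floor(within_rate * n_observed)` count of entries in each selected
#' column, emulating coverage loss in GC-extreme transcripts.
#'
#' @param m an [omics_matrix()].
#' @param covariates a `feature_covariates` object with `gc_content`.
#' @param top_frac fraction of features eligible (default 0.10).
#' @param within_rate fraction of entries masked within eligible columns
#'   (default 0.50).
#' @param seed integer seed.
#' @return A `masked_trial`.
#' @export
mask_high_gc <- function(m, covariates, top_frac = 0.10, within_rate = 0.50,
                         seed = 1) {
  stopifnot(is_omics_matrix(m))
  gc <- covariates$gc_content
  if (is.null(gc)) stop("covariates must supply gc_content")
  p <- ncol(m$values)
  if (length(gc) != p) stop("gc_content length must equal n_features")
  n_top <- round(top_frac * p)
  if (n_top < 1) stop("top_frac selects zero features")
  eligible <- order(-gc, seq_len(p))[seq_len(n_top)]
  idx <- mask_within_columns(m, eligible, within_rate, seed)
  new_masked_trial(m, idx, "high_gc", seed)
}

# mask floor(within_rate * n_observed) entries uniformly in each column
mask_within_columns <- function(m, cols, within_rate, seed) {
  picks <- with_seed(seed, lapply(cols, function(j) {
    obs <- which(m$mask[, j])
    k <- floor(within_rate * length(obs))
    if (k < 1) return(NULL)
    cbind(sort(obs[sample.int(length(obs), k)]), j)
  }))
  out <- do.call(rbind, picks)
  if (is.null(out) || nrow(out) == 0) stop("masking selected zero entries")
  out
}

#' Mask entire features
#'
#' Randomly selects `round(frac * n_features)` features and masks every
#' observed value in them — the scenario where a pre-processing pipeline
#' drops whole genes or CpG sites from some samples.
#'
#' @param m an [omics_matrix()].
#' @param frac fraction of features to remove entirely (default 0.05).
#' @param seed integer seed.
#' @return A `masked_trial`.
#' @export
mask_entire_features <- function(m, frac = 0.05, seed = 1) {
  stopifnot(is_omics_matrix(m))
  p <- ncol(m$values)
  k <- round(frac * p)
  if (k < 1) stop("frac * n_features rounds to zero")
  cols <- with_seed(seed, sort(sample.int(p, k)))
  idx <- do.call(rbind, lapply(cols, function(j) {
    obs <- which(m$mask[, j])
    cbind(obs, j)
  }))
  new_masked_trial(m, idx, "entire_features", seed)
}

#' Mask the lowest observed values (MNAR-low)
#'
#' The eligible set is the lowest `quantile` fraction of all observed
#' entries, ranked matrix-wide (not per feature; ties broken by feature
#' then sample index); `floor(within_rate * n_eligible)` of them are
#' masked uniformly. Emulates drop-out of lowly expressed genes at
#' shallow sequencing depth — the scenario the shift-corrected VAE
#' targets.
#'
#' @param m an [omics_matrix()].
#' @param quantile fraction of lowest observed entries eligible (default
#'   0.10).
#' @param within_rate fraction of the eligible set masked (default 0.50).
#' @param seed integer seed.
#' @return A `masked_trial`.
#' @export
mask_lowest_values <- function(m, quantile = 0.10, within_rate = 0.50,
                               seed = 1) {
  stopifnot(is_omics_matrix(m))
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  obs <- which(m$mask)
  n_elig <- floor(quantile * length(obs))
  if (n_elig < 1) stop("quantile selects zero entries")
  vals <- m$values[obs]
  # matrix-wide ranking; which() returns column-major order so the index
  # itself is the deterministic tie-break
  eligible <- obs[order(vals, obs)[seq_len(n_elig)]]
  k <- floor(within_rate * n_elig)
  if (k < 1) stop("within_rate selects zero entries")
  picked <- with_seed(seed, sort(eligible[sample.int(n_elig, k)]))
  idx <- cbind((picked - 1) %% nrow(m$values) + 1,
               (picked - 1) %/% nrow(m$values) + 1)
  new_masked_trial(m, idx, "lowest_values", seed)
}

#' Mask values within low-coverage features
#'
#' Features whose read coverage is strictly below `threshold` are
#' eligible; within each, `floor(within_rate * n_observed)` entries are
#' masked. Emulates methylation calls discarded for insufficient
#' bisulfite read depth.
#'
#' @param m an [omics_matrix()].
#' @param covariates a `feature_covariates` object with `coverage`.
#' @param threshold coverage cut-off in reads (default 6; strict `<`).
#' @param within_rate fraction masked within eligible columns (default
#'   0.50).
#' @param seed integer seed.
#' @return A `masked_trial`.
#' @export
mask_low_coverage <- function(m, covariates, threshold = 6,
                              within_rate = 0.50, seed = 1) {
  stopifnot(is_omics_matrix(m))
  cov <- covariates$coverage
  if (is.null(cov)) stop("covariates must supply coverage")
  if (length(cov) != ncol(m$values))
    stop("coverage length must equal n_features")
  eligible <- which(cov < threshold)
  if (length(eligible) == 0)
    stop(sprintf("no features with coverage below %s", threshold))
  idx <- mask_within_columns(m, eligible, within_rate, seed)
  new_masked_trial(m, idx, "low_coverage", seed)
}

#' Describe a masking scenario
#'
#' Bundles a mechanism with its parameters so [run_trials()] and the
#' benchmark driver can apply it repeatedly. `rate` is the
#' mechanism-specific primary fraction: the per-row rate for `mcar`, the
#' top GC fraction for `high_gc`, the feature fraction for
#' `entire_features`, and the value quantile for `lowest_values`.
#'
#' @param mechanism one of `"mcar"`, `"high_gc"`, `"entire_features"`,
#'   `"lowest_values"`, `"low_coverage"`.
#' @param rate primary fraction (see above); unused for `low_coverage`.
#' @param within_rate fraction masked within the eligible set.
#' @param threshold coverage threshold for `low_coverage`.
#' @param seed base seed for [run_trials()].
#' @return A `mask_spec` list.
#' @export
mask_spec <- function(mechanism = c("mcar", "high_gc", "entire_features",
                                    "lowest_values", "low_coverage"),
                      rate = 0.10, within_rate = 0.50, threshold = 6,
                      seed = 1) {
  mechanism <- match.arg(mechanism)
  if (!is.null(rate) && (rate <= 0 || rate >= 1)) stop("rate must be in (0, 1)")
  if (within_rate <= 0 || within_rate > 1) stop("within_rate must be in (0, 1]")
  structure(list(mechanism = mechanism, rate = rate,
                 within_rate = within_rate, threshold = threshold,
                 seed = as.integer(seed)),
            class = "mask_spec")
}

#' Apply a masking scenario once
#'
#' @param m an [omics_matrix()].
#' @param spec a [mask_spec()].
#' @param covariates `feature_covariates`, required for `high_gc` and
#'   `low_coverage`.
#' @param seed overrides `spec$seed` when given.
#' @return A `masked_trial`.
#' @export
apply_mask <- function(m, spec, covariates = NULL, seed = NULL) {
  stopifnot(inherits(spec, "mask_spec"))
  s <- if (is.null(seed)) spec$seed else seed
  switch(spec$mechanism,
    mcar = mask_mcar(m, rate = spec$rate, seed = s),
    high_gc = mask_high_gc(m, covariates, top_frac = spec$rate,
                           within_rate = spec$within_rate, seed = s),
    entire_features = mask_entire_features(m, frac = spec$rate, seed = s),
    lowest_values = mask_lowest_values(m, quantile = spec$rate,
                                       within_rate = spec$within_rate,
                                       seed = s),
    low_coverage = mask_low_coverage(m, covariates,
                                     threshold = spec$threshold,
                                     within_rate = spec$within_rate,
                                     seed = s)
  )
}

#' Run repeated random masking trials
#'
#' Applies one scenario `n_trials` times with per-trial seeds derived
#' deterministically from the base seed, the protocol used to average
#' imputation performance over masking randomness.
#'
#' @inheritParams apply_mask
#' @param n_trials number of trials (default 10).
#' @return A list of `masked_trial` objects.
#' @export
run_trials <- function(m, spec, n_trials = 10, covariates = NULL) {
  stopifnot(n_trials >= 1)
  seeds <- derive_seeds(spec$seed, n_trials)
  lapply(seeds, function(s) apply_mask(m, spec, covariates, seed = s))
}

#' Reconstruct the original matrix from a masked trial
#'
#' Inserts the stored truth back at the masked index — the round-trip
#' identity every mechanism must satisfy.
#'
#' @param trial a `masked_trial`.
#' @return An [omics_matrix()] equal to the input of the masking call.
#' @export
reconstruct_from_trial <- function(trial) {
  m <- trial$corrupted
  v <- m$values
  mk <- m$mask
  v[trial$masked_index] <- trial$truth
  mk[trial$masked_index] <- TRUE
  replace_values(m, v, mask = mk)
}
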