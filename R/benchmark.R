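#' Run the full masking-and-imputation benchmark
#'
#' Reproduces the simulation protocol end to end at any scale: split the
#' samples into training and hold-out test sets, train one VAE on the
#' complete training data, apply each masking scenario to the test data
#' in `n_trials` independent trials, impute every trial with every
#' requested method, and score each against the withheld truth. Methods
#' are compared per scenario with paired Wilcoxon tests over the shared
#' trials.
#'
#' @param m an [omics_matrix()] of complete data; if `NULL`, synthetic
#'   low-rank data are generated from `synth`.
#' @param covariates `feature_covariates` for the GC / coverage
#'   scenarios; generated alongside synthetic data when `m` is `NULL`.
#' @param synth arguments for [generate_matrix()] used when `m` is
#'   `NULL`.
#' @param scenarios named list of [mask_spec()]s.
#' @param methods subset of `"mean"`, `"knn"`, `"svd"`, `"random"`,
#'   `"vae"`.
#' @param n_trials masking trials per scenario (default 10).
#' @param train_frac fraction of samples used for training (default
#'   0.8).
#' @param vae_args extra arguments for [vae()] (architecture, epochs,
#'   ...).
#' @param knn_k neighbours for [impute_knn()].
#' @param svd_rank rank for [impute_svd()] (`NULL` = full).
#' @param seed global seed; every split, mask and fill derives from it.
#' @param error_variant see [imputation_error()].
#' @return A `benchmark_result`: list with `results` (long data.frame:
#'   scenario, method, trial, error), `reports` (per-scenario
#'   [eval_report()]), `model` (the fitted VAE, if used), `split`, and
#'   the call parameters.
#' @examples
#' \donttest{
#' bm <- run_benchmark(synth = list(n_samples = 80, n_features = 60,
#'                                  latent_rank = 4, noise_sd = 0.3),
#'                     scenarios = list(mcar_10 = mask_spec("mcar", 0.10)),
#'                     methods = c("mean", "knn"), n_trials = 3, seed = 1)
#' bm$reports$mcar_10
#' }
#' @export
run_benchmark <- function(m = NULL, covariates = NULL,
                          synth = list(n_samples = 300, n_features = 500,
                                       latent_rank = 10, noise_sd = 0.3),
                          scenarios = list(mcar_10 = mask_spec("mcar", 0.10)),
                          methods = c("mean", "knn", "svd", "vae"),
                          n_trials = 10, train_frac = 0.8,
                          vae_args = list(), knn_k = 10, svd_rank = NULL,
                          seed = 1, error_variant = "as_printed") {
  methods <- match.arg(methods, c("mean", "knn", "svd", "random", "vae"),
                       several.ok = TRUE)
  if (length(scenarios) == 0 || is.null(names(scenarios)))
    stop("at least one named scenario is required")
  if (is.null(m)) {
    g <- do.call(generate_matrix, c(synth, list(seed = seed)))
    m <- g$matrix
    if (is.null(covariates))
      covariates <- generate_feature_covariates(m, seed = seed + 1L)
  }
  split <- split_samples(m, fractions = c(train_frac, 1 - train_frac),
                         seed = seed)
  train <- m[split$train_idx, ]
  test <- m[split$test_idx, ]

  model <- NULL
  if ("vae" %in% methods)
    model <- do.call(vae, c(list(x = train, seed = seed), vae_args))

  rows <- list()
  reports <- list()
  for (sc in names(scenarios)) {
    spec <- scenarios[[sc]]
    spec$seed <- derive_seeds(seed + match(sc, names(scenarios)), 1)
    trials <- run_trials(test, spec, n_trials = n_trials,
                         covariates = covariates)
    errs <- lapply(methods, function(mt) rep(NA_real_, n_trials))
    names(errs) <- methods
    for (ti in seq_along(trials)) {
      trial <- trials[[ti]]
      fill_seed <- derive_seeds(trial$seed, 1)
      for (mt in methods) {
        err <- tryCatch({
          res <- switch(mt,
            mean = impute_mean(train, trial$corrupted),
            knn = suppressWarnings(
              impute_knn(train, trial$corrupted, k = knn_k)),
            svd = suppressWarnings(
              impute_svd(train, trial$corrupted, rank = svd_rank)),
            random = impute_random(train, trial$corrupted, seed = fill_seed),
            vae = impute_vae(model, trial$corrupted, seed = fill_seed))
          trial_error(trial, res, variant = error_variant)
        }, error = function(e) {
          warning(sprintf("%s failed on %s trial %d: %s",
                          mt, sc, ti, conditionMessage(e)))
          NA_real_
        })
        errs[[mt]][ti] <- err
        rows[[length(rows) + 1]] <-
          data.frame(scenario = sc, method = mt, trial = ti, error = err)
      }
    }
    reports[[sc]] <- eval_report(errs, variant = error_variant)
  }
  structure(list(results = do.call(rbind, rows), reports = reports,
                 model = model, split = split, scenarios = scenarios,
                 methods = methods, n_trials = n_trials, seed = seed,
                 error_variant = error_variant),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark_result: %d scenario(s) x %d method(s) x %d trial(s)\n",
              length(x$reports), length(x$methods), x$n_trials))
  for (sc in names(x$reports)) {
    cat("\n--", sc, "--\n")
    print(x$reports[[sc]])
  }
  invisible(x)
}

#' Sweep the KL regularization weight beta
#'
#' Trains one VAE per `beta` on the training split and scores each on
#' the same masking trials, isolating the effect of latent-space
#' regularization strength on imputation accuracy.
#'
#' @inheritParams run_benchmark
#' @param betas KL weights to compare (default `c(0, 1, 4, 10)`).
#' @param scenario a single [mask_spec()] (default MCAR 10%).
#' @return list with `results` (data.frame: beta, trial, error),
#'   `summary` (mean error per beta), and `models`.
#' @export
beta_sweep <- function(m = NULL,
                       synth = list(n_samples = 300, n_features = 500,
                                    latent_rank = 10, noise_sd = 0.3),
                       betas = c(0, 1, 4, 10),
                       scenario = mask_spec("mcar", 0.10),
                       n_trials = 5, train_frac = 0.8,
                       vae_args = list(), seed = 1,
                       error_variant = "as_printed") {
  if (is.null(m)) {
    g <- do.call(generate_matrix, c(synth, list(seed = seed)))
    m <- g$matrix
  }
  split <- split_samples(m, fractions = c(train_frac, 1 - train_frac),
                         seed = seed)
  train <- m[split$train_idx, ]
  test <- m[split$test_idx, ]
  scenario$seed <- derive_seeds(seed, 1)
  trials <- run_trials(test, scenario, n_trials = n_trials)

  rows <- list()
  models <- list()
  for (b in betas) {
    fit <- do.call(vae, c(list(x = train, beta = b, seed = seed), vae_args))
    models[[as.character(b)]] <- fit
    for (ti in seq_along(trials)) {
      res <- impute_vae(fit, trials[[ti]]$corrupted,
                        seed = derive_seeds(trials[[ti]]$seed, 1))
      rows[[length(rows) + 1]] <- data.frame(
        beta = b, trial = ti,
        error = trial_error(trials[[ti]], res, variant = error_variant))
    }
  }
  results <- do.call(rbind, rows)
  summary_df <- stats::aggregate(error ~ beta, data = results, FUN = mean)
  list(results = results, summary = summary_df, models = models)
}
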