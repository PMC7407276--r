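test_that("KNN matches hand-computed toys: k = 1, zero distance, ties", {
  # zero-distance candidate: target (1, NA); candidates (1, 10) and (3, 20)
  train <- omics_matrix(matrix(c(1, 10, 3, 20), 2, 2, byrow = TRUE))
  target <- omics_matrix(matrix(c(1, NA), 1, 2))
  res <- impute_knn(train, target, k = 2)
  expect_equal(res$completed$values[1, 2], 10)

  # k = 1: exactly the nearest candidate's value
  res1 <- impute_knn(train, target, k = 1)
  expect_equal(res1$completed$values[1, 2], 10)

  # two equidistant candidates holding 4 and 6 -> 5
  train2 <- omics_matrix(matrix(c(2, 4, 0, 6), 2, 2, byrow = TRUE))
  target2 <- omics_matrix(matrix(c(1, NA), 1, 2))
  res2 <- impute_knn(train2, target2, k = 2)
  expect_equal(res2$completed$values[1, 2], 5)
})

test_that("KNN agrees with an exhaustive brute-force search on a 6 x 5 toy", {
  set.seed(41)
  train <- omics_matrix(matrix(rnorm(15), 3, 5))
  v <- matrix(rnorm(15), 3, 5)
  v[cbind(c(1, 2, 3, 3), c(2, 4, 1, 5))] <- NA
  corrupted <- omics_matrix(v)
  for (k in c(1, 3, 10)) {
    got <- suppressWarnings(impute_knn(train, corrupted, k = k))
    want <- brute_knn(train, corrupted, k)
    expect_equal(got$completed$values, want, tolerance = 1e-12)
  }
})

test_that("KNN warns when candidates are scarce and falls back to the mean", {
  # candidates exist at the target feature but share no observed feature
  # with the target sample, so none is usable
  train <- omics_matrix(matrix(c(NA, NA, NA, 1, 2, 3), 3, 2))
  corrupted <- omics_matrix(matrix(c(1.5, NA), 1, 2))
  expect_warning(res <- impute_knn(train, corrupted, k = 10),
                 "no candidate")
  expect_equal(res$completed$values[1, 2], 2)  # train mean of feature 2

  train2 <- omics_matrix(matrix(c(1, 2, 10, 20), 2, 2))
  expect_warning(res2 <- impute_knn(train2, corrupted, k = 10, pool = "train"),
                 "fewer than k")
})

test_that("SVD imputation recovers exact low-rank structure", {
  u <- c(1, 2, 3, 4); v <- c(2, -1, 0.5)
  X <- outer(u, v)
  Xc <- X; Xc[2, 3] <- NA
  res <- impute_svd(NULL, omics_matrix(Xc), rank = 1)
  expect_lt(abs(res$completed$values[2, 3] - X[2, 3]), 1e-8)

  # huge tolerance: exactly one iteration
  res1 <- impute_svd(NULL, omics_matrix(Xc), rank = 1, tol = 1e12)
  expect_equal(res1$iterations_run, 1L)

  # iterative refinement shrinks the total change monotonically
  set.seed(42)
  Z <- matrix(rnorm(60), 20, 3) %*% matrix(rnorm(24), 3, 8)
  Zc <- Z
  Zc[sample(length(Z), 30)] <- NA
  res_it <- impute_svd(NULL, omics_matrix(Zc), rank = 3, tol = 1e-10,
                       max_iter = 25)
  d <- res_it$per_iteration_delta
  if (length(d) > 1) expect_true(all(diff(d) <= 1e-8))
  expect_error(impute_svd(NULL, omics_matrix(Zc), rank = 50), "rank")
})

test_that("mean imputation fills train feature means", {
  train <- omics_matrix(matrix(c(1, 2, 3, 5, 5, 5), 3, 2))
  corrupted <- omics_matrix(matrix(c(NA, 9, 9, NA), 2, 2))
  res <- impute_mean(train, corrupted)
  expect_equal(res$completed$values[1, 1], 2)
  expect_equal(res$completed$values[2, 2], 5)
  full <- random_omics(3, 4)
  expect_identical(impute_mean(train = full, corrupted = full)$completed$values,
                   full$values)
})

test_that("random imputation draws from the train feature distribution", {
  set.seed(43)
  train <- omics_matrix(matrix(rnorm(600, mean = 3, sd = 2), 300, 2))
  v <- matrix(NA_real_, 5000, 2)
  v[, 2] <- 0
  corrupted <- omics_matrix(v)
  res <- impute_random(train, corrupted, seed = 44)
  fills <- res$completed$values[, 1]
  s <- fit_scaler(train)
  expect_lt(abs(mean(fills) - s$mean[1]), 3 * s$sd[1] / sqrt(5000) * 3)
  expect_identical(unname(res$completed$values[, 2]), v[, 2])
  res2 <- impute_random(train, corrupted, seed = 44)
  expect_identical(res$completed$values, res2$completed$values)
})

test_that("VAE imputation preserves observed entries and converges", {
  fit <- small_vae()
  test_m <- generate_matrix(n_samples = 40, n_features = 40, latent_rank = 3,
                            noise_sd = 0.2, seed = 8)$matrix
  trial <- mask_mcar(test_m, 0.10, seed = 9)
  res <- impute_vae(fit, trial$corrupted, n_iterations = 3, seed = 10)
  expect_observed_preserved(res, trial$corrupted)
  expect_length(res$per_iteration_delta, 3)
  # later refinements are smaller than the first fill adjustment
  expect_lt(res$per_iteration_delta[3], res$per_iteration_delta[1])

  # fully observed input comes back unchanged
  res_full <- impute_vae(fit, test_m, seed = 1)
  expect_identical(res_full$completed$values, test_m$values)
  expect_equal(res_full$iterations_run, 0L)

  wrong <- generate_matrix(10, 13, 2, 0.1, seed = 1)$matrix
  expect_error(impute_vae(fit, wrong), "features")
})

test_that("every imputer preserves observed values bit-for-bit", {
  fit <- small_vae()
  train <- fit$data
  test_m <- generate_matrix(n_samples = 30, n_features = 40, latent_rank = 3,
                            noise_sd = 0.2, seed = 12)$matrix
  covs <- generate_feature_covariates(test_m, seed = 12)
  trials <- list(mcar = mask_mcar(test_m, 0.10, seed = 2),
                 lowest = mask_lowest_values(test_m, seed = 3),
                 whole = mask_entire_features(test_m, seed = 4))
  for (tr in trials) {
    results <- list(
      mean = impute_mean(train, tr$corrupted),
      knn = suppressWarnings(impute_knn(train, tr$corrupted)),
      svd = impute_svd(train, tr$corrupted),
      random = impute_random(train, tr$corrupted, seed = 5),
      vae = impute_vae(fit, tr$corrupted, seed = 6))
    for (res in results) expect_observed_preserved(res, tr$corrupted)
  }
})

test_that("shift-lambda selection returns the grid minimiser", {
  g <- generate_matrix(n_samples = 80, n_features = 30, latent_rank = 2,
                       noise_sd = 0.2, seed = 13)
  sp <- split_samples(g$matrix, c(0.75, 0.25), seed = 13)
  train <- g$matrix[sp$train_idx, ]
  val <- g$matrix[sp$test_idx, ]
  tiny_args <- list(hidden_dims = 8, latent_dim = 2, learning_rate = 1e-3,
                    batch_size = 30, epochs = 30, keep_data = FALSE)
  lam0 <- select_shift_lambda(train, val, lambda_grid = 0,
                              vae_args = tiny_args, seed = 14)
  expect_equal(as.numeric(lam0), 0)
  expect_length(attr(lam0, "errors"), 1)
  expect_error(select_shift_lambda(train, val, lambda_grid = numeric(0)),
               "non-empty")
})
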