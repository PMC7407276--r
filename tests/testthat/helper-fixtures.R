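# Shared fixtures, built in code. Expensive objects (the benchmark-scale
# data and trained VAE) are cached per session so several test files can
# reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small deterministic matrix with a known missing pattern
tiny_omics <- function(modality = "generic") {
  v <- matrix(c(1, 2, 3,
                4, NA, 6,
                7, 8, 9,
                10, 11, NA), nrow = 4, byrow = TRUE)
  omics_matrix(v, modality = modality)
}

# fully observed random matrix for round-trip style checks
random_omics <- function(n = 5, p = 7, seed = 11) {
  set.seed(seed)
  omics_matrix(matrix(rnorm(n * p), n, p))
}

# desk-scale VAE settings used wherever a net must actually learn
desk_vae_args <- function(epochs = 100) {
  list(hidden_dims = c(64, 32), latent_dim = 8, learning_rate = 1e-3,
       batch_size = 64, epochs = epochs, keep_data = FALSE)
}

# the benchmark-scale study conditions: n=300, p=500, rank 10, noise 0.3
bench_data <- function() {
  cached("bench_data", {
    g <- generate_matrix(n_samples = 300, n_features = 500,
                         latent_rank = 10, noise_sd = 0.3, seed = 101)
    sp <- split_samples(g$matrix, fractions = c(0.8, 0.2), seed = 101)
    list(g = g, split = sp,
         train = g$matrix[sp$train_idx, ],
         test = g$matrix[sp$test_idx, ])
  })
}

# one VAE trained on the benchmark training split, reused across tests
bench_vae <- function() {
  cached("bench_vae", {
    bd <- bench_data()
    do.call(vae, c(list(x = bd$train, seed = 101), desk_vae_args()))
  })
}

# tiny trained model for interface-level tests (seconds)
small_vae <- function() {
  cached("small_vae", {
    g <- generate_matrix(n_samples = 80, n_features = 40, latent_rank = 3,
                         noise_sd = 0.2, seed = 7)
    vae(g$matrix, hidden_dims = 16, latent_dim = 3, learning_rate = 1e-3,
        batch_size = 32, epochs = 60, seed = 7)
  })
}

# brute-force reference: weighted KNN by explicit loops, following the
# definition directly (shared-feature-normalised Euclidean distance,
# candidates observed at the target feature, 1/d weights, zero-distance
# candidates averaged unweighted)
brute_knn <- function(train, corrupted, k) {
  pool_v <- rbind(train$values, corrupted$values)
  pool_m <- rbind(train$mask, corrupted$mask)
  n_train <- nrow(train$values)
  out <- corrupted$values
  for (i in seq_len(nrow(corrupted$values))) {
    for (j in seq_len(ncol(corrupted$values))) {
      if (corrupted$mask[i, j]) next
      cand <- c(); dist <- c()
      for (c_ in seq_len(nrow(pool_v))) {
        if (c_ == n_train + i) next
        if (!pool_m[c_, j]) next
        shared <- corrupted$mask[i, ] & pool_m[c_, ]
        if (!any(shared)) next
        d <- sqrt(sum((corrupted$values[i, shared] -
                         pool_v[c_, shared])^2) / sum(shared))
        cand <- c(cand, c_); dist <- c(dist, d)
      }
      sel <- order(dist)[seq_len(min(k, length(cand)))]
      dsel <- dist[sel]; vsel <- pool_v[cand[sel], j]
      out[i, j] <- if (any(dsel == 0)) mean(vsel[dsel == 0])
                   else sum(vsel / dsel) / sum(1 / dsel)
    }
  }
  out
}

expect_observed_preserved <- function(result, corrupted) {
  obs <- corrupted$mask
  expect_identical(result$completed$values[obs], corrupted$values[obs])
  expect_true(all(result$completed$mask))
  expect_false(anyNA(result$completed$values))
}
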