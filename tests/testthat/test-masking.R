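test_that("MCAR masks an exact per-row count, uniformly and reproducibly", {
  m <- random_omics(10, 20, seed = 1)
  tr <- mask_mcar(m, rate = 0.30, seed = 2)
  per_row <- rowSums(!tr$corrupted$mask)
  expect_true(all(per_row == 6))
  expect_equal(nrow(tr$masked_index), 60)

  tr5 <- mask_mcar(m, rate = 0.05, seed = 2)
  expect_true(all(rowSums(!tr5$corrupted$mask) == 1))

  expect_identical(mask_mcar(m, 0.3, seed = 9)$masked_index,
                   mask_mcar(m, 0.3, seed = 9)$masked_index)
  expect_false(identical(mask_mcar(m, 0.3, seed = 9)$masked_index,
                         mask_mcar(m, 0.3, seed = 10)$masked_index))
  expect_error(mask_mcar(m, rate = 0.01, seed = 1), "zero")
})

test_that("masking never selects entries that are already missing", {
  m <- tiny_omics()   # has 2 pre-existing NAs
  tr <- mask_mcar(m, rate = 0.4, seed = 3)
  pre_missing <- which(!m$mask)
  expect_length(intersect(pre_missing, which(is.na(tr$corrupted$values))),
                length(pre_missing))
  # none of the newly masked indices coincide with pre-existing NAs
  new_idx <- tr$masked_index
  expect_true(all(m$mask[new_idx]))
})

test_that("high-GC masking hits only the top-GC columns at the exact count", {
  m <- random_omics(50, 100, seed = 4)
  covs <- list(gc_content = seq(0.2, 0.8, length.out = 100))
  tr <- mask_high_gc(m, covs, top_frac = 0.10, within_rate = 0.50, seed = 5)
  expect_equal(nrow(tr$masked_index), 250)            # 10 cols x 25 each
  eligible <- order(-covs$gc_content, seq_len(100))[1:10]
  expect_true(all(tr$masked_index[, 2] %in% eligible))
  # ties at the cutoff broken by ascending feature index
  covs_tied <- list(gc_content = rep(c(0.8, 0.2), each = 50))
  tr2 <- mask_high_gc(m, covs_tied, top_frac = 0.10, seed = 5)
  expect_true(all(unique(tr2$masked_index[, 2]) %in% 1:10))
  expect_error(mask_high_gc(m, list(coverage = 1:100)), "gc_content")
})

test_that("entire-feature masking removes whole columns and nothing else", {
  m <- random_omics(40, 100, seed = 6)
  tr <- mask_entire_features(m, frac = 0.05, seed = 7)
  expect_equal(nrow(tr$masked_index), 200)            # 5 cols x 40 rows
  masked_cols <- unique(tr$masked_index[, 2])
  expect_length(masked_cols, 5)
  expect_true(all(colSums(tr$corrupted$mask[, masked_cols]) == 0))
  expect_true(all(colSums(tr$corrupted$mask[, -masked_cols]) == 40))
  expect_error(mask_entire_features(m, frac = 0.001), "zero")
})

test_that("lowest-value masking works matrix-wide on order statistics", {
  set.seed(8)
  m <- omics_matrix(matrix(sample(1:100), 10, 10))
  tr <- mask_lowest_values(m, quantile = 0.10, within_rate = 0.50, seed = 9)
  expect_equal(nrow(tr$masked_index), 5)
  expect_true(all(tr$truth %in% 1:10))  # among the 10 smallest, matrix-wide

  # matrix-wide, not per-feature: concentrate small values in one column
  v <- matrix(100, 10, 10)
  v[, 1] <- 1:10
  m2 <- omics_matrix(v)
  tr2 <- mask_lowest_values(m2, quantile = 0.10, within_rate = 1, seed = 9)
  expect_true(all(tr2$masked_index[, 2] == 1))
  expect_true(all(tr2$truth <= 10))
})

test_that("low-coverage masking uses a strict threshold on eligible features", {
  m <- random_omics(10, 4, seed = 10)
  covs <- list(coverage = c(2L, 6L, 5L, 9L))
  tr <- mask_low_coverage(m, covs, threshold = 6, within_rate = 0.50,
                          seed = 11)
  expect_setequal(unique(tr$masked_index[, 2]), c(1L, 3L))
  expect_equal(nrow(tr$masked_index), 10)             # 2 cols x 5 each
  expect_error(mask_low_coverage(m, covs, threshold = 0), "no features")
})

test_that("every mechanism reconstructs the original matrix exactly", {
  m <- random_omics(50, 100, seed = 12)
  covs <- generate_feature_covariates(m, seed = 12)
  trials <- list(
    mask_mcar(m, 0.10, seed = 1),
    mask_high_gc(m, covs, seed = 2),
    mask_entire_features(m, seed = 3),
    mask_lowest_values(m, seed = 4),
    mask_low_coverage(m, covs, threshold = 8, seed = 5))
  for (tr in trials) {
    rec <- reconstruct_from_trial(tr)
    expect_identical(rec$values, m$values)
    expect_identical(rec$mask, m$mask)
    expect_equal(sum(!tr$corrupted$mask), nrow(tr$masked_index))
  }
})

test_that("trial batteries are reproducible and distinct across trials", {
  m <- random_omics(20, 30, seed = 13)
  spec <- mask_spec("mcar", rate = 0.10, seed = 77)
  trials <- run_trials(m, spec, n_trials = 10)
  expect_length(trials, 10)
  masks <- lapply(trials, function(t) t$masked_index)
  expect_equal(length(unique(lapply(masks, c))), 10)   # all distinct
  again <- run_trials(m, spec, n_trials = 10)
  expect_identical(masks, lapply(again, function(t) t$masked_index))
  expect_length(run_trials(m, spec, n_trials = 1), 1)
})

test_that("mask trial truth files round-trip through text", {
  m <- random_omics(8, 6, seed = 14)
  tr <- mask_mcar(m, 0.2, seed = 15)
  mp <- withr::local_tempfile(fileext = ".tsv")
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_masked_trial(tr, mp, tp)
  corrupted <- read_omics_matrix(mp)
  back <- read_masked_trial(corrupted, tp)
  expect_equal(back$truth, tr$truth)
  expect_equal(back$masked_index[, "sample"], tr$masked_index[, "sample"])
  # text serialisation keeps 15 significant digits
  expect_equal(reconstruct_from_trial(back)$values, m$values,
               tolerance = 1e-12)
})
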