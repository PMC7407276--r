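# vaeimpute

Missing-value imputation for bulk transcriptome and methylome matrices
with a beta-variational auto-encoder, alongside the classical
comparators (weighted KNN, iterative SVD, feature-mean and random-draw
imputation), a full MCAR/MNAR masking simulation battery, and
evaluation utilities for both reconstruction error and downstream
clinical concordance.

## Who this is for

Genomic data sets — RNA-seq expression matrices, WGBS methylation
matrices — routinely contain missing values from pipeline filtering,
shallow sequencing and low bisulfite coverage, while most downstream
analyses need complete matrices. Much of that missingness is **not at
random**: it depends on the unobserved value (lowly expressed genes
drop out) or on feature covariates (GC content, read coverage). This
package is for practitioners and method developers who need to impute
such matrices, and to *evaluate* imputation honestly under the
missingness mechanisms that actually occur.

## The method

A Gaussian VAE is trained on complete, z-scored samples by minimising
the negative ELBO with a weighted KL term

    L = -E[ log P(x|z) ] + beta * KL( Q(z|x) || N(0, I) ),

where encoder and decoder are ReLU MLPs outputting means and diagonal
log-variances, optimised with Adam through the reparameterization trick
`z = mu + sigma * eps`. Missing entries of new samples are filled by an
iterative encode–decode loop (posterior mean in, decoder mean out,
observed entries never touched; 3 passes by default).

For data missing preferentially at **low values**, the shift-corrected
likelihood models observed training data as `N(mu + lambda*sigma,
sigma)`, so the decoder mean targets the low-shifted missing-data
distribution; `lambda` is selected once on validation data by
simulating the lowest-value scenario (`select_shift_lambda()`).

The reported imputation error follows the per-entry formula
`sum(sqrt((x - x')^2)) / n` — algebraically the mean absolute error —
as variant `"as_printed"`; the conventional quadratic RMSE is available
as `"quadratic"`.

## Worked example

Synthetic low-rank data stand in for a cohort: 300 samples, 500
features, 10 latent factors, noise sd 0.3. Train on 240 complete
samples, corrupt the 60 held-out samples with 10% missing-completely-
at-random entries per row, impute, and score against the withheld
truth.

```r
library(vaeimpute)

g  <- generate_matrix(n_samples = 300, n_features = 500, latent_rank = 10,
                      noise_sd = 0.3, seed = 1)
sp <- split_samples(g$matrix, fractions = c(0.8, 0.2), seed = 1)
train <- g$matrix[sp$train_idx, ]
test  <- g$matrix[sp$test_idx, ]

fit <- vae(train, hidden_dims = c(64, 32), latent_dim = 8,
           learning_rate = 1e-3, batch_size = 64, epochs = 100, seed = 1)
fit
#> beta-VAE: 500 -> [64, 32] -> 8 -> [32, 64] -> 500
#>   beta = 1, shift_lambda = 0, learned decoder variance
#>   trained 100 epochs (lr 0.001, batch 64); final loss 343.8028

trial <- mask_mcar(test, rate = 0.10, seed = 2)
trial
#> masked_trial (mcar): 3000 entries masked of 60 x 500 matrix

res <- impute_vae(fit, trial$corrupted, seed = 2)
trial_error(trial, res)                                        # 0.5772173
trial_error(trial, impute_mean(train, trial$corrupted))        # 0.8528927
trial_error(trial, impute_knn(train, trial$corrupted, k = 10)) # 0.4942107
trial_error(trial, impute_svd(train, trial$corrupted))         # 0.3685598
```

The error is the mean absolute deviation between imputed values and the
withheld truths on the z-scored scale of the data: the structure-blind
mean-imputation floor sits at 0.85, while the VAE (0.58), KNN (0.49)
and iterative SVD (0.37) all exploit the cross-feature correlation.
`run_benchmark()` wraps this protocol over many scenarios, methods and
trials and adds paired Wilcoxon comparisons;
`spearman_vs_grade()` / `cox_coefficients()` /
`concordance_of_coefficients()` measure how well imputation preserves
clinical associations.

A command-line interface over the same functions (subcommands
`simulate`, `mask`, `train`, `impute`, `evaluate`, `benchmark`) is
installed at `system.file("cli", "vaeimpute", package = "vaeimpute")`.

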