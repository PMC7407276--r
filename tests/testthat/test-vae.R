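test_that("KL divergence closed form matches hand values and Monte Carlo", {
  expect_equal(kl_divergence(0, 0), 0)
  expect_equal(kl_divergence(1, 0), 0.5)
  # matrix input: one value per row
  expect_equal(kl_divergence(matrix(c(0, 1), 2, 1), matrix(0, 2, 1)),
               c(0, 0.5))

  set.seed(21)
  for (i in 1:3) {
    mu <- runif(1, 0.5, 2) * sample(c(-1, 1), 1)
    lv <- runif(1, -1, 1)
    z <- rnorm(1e6, mean = mu, sd = exp(0.5 * lv))
    # E_q[log q(z) - log p(z)] estimated by simple Monte Carlo
    mc <- mean(0.5 * (z^2 - lv - (z - mu)^2 / exp(lv)))
    expect_lt(abs(kl_divergence(mu, lv) - mc) / mc, 0.01)
  }
  set.seed(22)
  expect_true(all(kl_divergence(matrix(rnorm(40), 10, 4),
                                matrix(rnorm(40), 10, 4)) >= 0))
})

test_that("reparameterization reproduces the posterior moments", {
  expect_equal(reparameterize(c(1, 2), c(0.3, -0.2), c(0, 0)), c(1, 2))
  expect_equal(reparameterize(1.5, 0, 1), 2.5)
  set.seed(23)
  mu <- 1.3; lv <- 0.7
  z <- reparameterize(rep(mu, 1e5), rep(lv, 1e5), rnorm(1e5))
  expect_lt(abs(mean(z) - mu) / abs(mu), 0.03)
  expect_lt(abs(var(z) - exp(lv)) / exp(lv), 0.03)
})

test_that("shift-corrected reconstruction NLL has the Gaussian geometry", {
  p <- 4
  x <- rnorm(p)
  expect_equal(reconstruction_nll(x, x, rep(0, p), shift_lambda = 0),
               p * 0.5 * log(2 * pi))
  # shifting the data by exactly lambda*sigma reproduces the unshifted NLL
  expect_equal(reconstruction_nll(x + 1, x, rep(0, p), shift_lambda = 1),
               reconstruction_nll(x, x, rep(0, p), shift_lambda = 0))
  # NLL minimised over x at mu + lambda*sigma
  f <- function(xx) reconstruction_nll(xx, 0.3, 0.4, shift_lambda = 1.2)
  opt <- optimize(f, c(-5, 5))$minimum
  expect_equal(opt, 0.3 + 1.2 * exp(0.2), tolerance = 1e-4)
})

test_that("training likelihood is shift-equivariant in the decoder mean", {
  # with sigma fixed (logvar = 0), the optimal mu for data shifted by
  # +c*sigma under lambda = c equals the optimal mu for the raw data
  # under lambda = 0
  set.seed(24)
  x <- rnorm(30, mean = 1.7)
  c_shift <- 0.8
  nll <- function(mu, data, lam)
    sum(vapply(data, function(xi)
      reconstruction_nll(xi, mu, 0, shift_lambda = lam), numeric(1)))
  mu_raw <- optimize(nll, c(-10, 10), data = x, lam = 0)$minimum
  mu_shifted <- optimize(nll, c(-10, 10), data = x + c_shift,
                         lam = c_shift)$minimum
  expect_equal(mu_shifted, mu_raw, tolerance = 1e-5)
})

test_that("elbo components are consistent and linear in beta", {
  fit <- small_vae()
  x <- apply_scaler(fit$data, fit$scaler)$values[1:10, ]
  eps <- matrix(0.5, 10, fit$config$latent_dim)
  l0 <- elbo_loss(fit, x, beta = 0, eps = eps)
  l1 <- elbo_loss(fit, x, beta = 1, eps = eps)
  l4 <- elbo_loss(fit, x, beta = 4, eps = eps)
  expect_equal(l0$loss, l0$recon)
  expect_equal(l4$loss - l1$loss, 3 * l1$kl, tolerance = 1e-10)
  expect_true(is.finite(l1$loss))
})

test_that("encoder is deterministic with the configured geometry", {
  fit <- small_vae()
  x <- apply_scaler(fit$data, fit$scaler)$values[3, ]
  e1 <- encode(fit, x)
  e2 <- encode(fit, x)
  expect_identical(e1, e2)
  expect_identical(dim(e1$mu), c(1L, fit$config$latent_dim))
  expect_identical(dim(e1$logvar), c(1L, fit$config$latent_dim))
  x_na <- x; x_na[2] <- NA
  expect_error(encode(fit, x_na), "pre-fill")
  d <- decode(fit, e1$mu)
  expect_identical(dim(d$mu), c(1L, fit$config$input_dim))
})

test_that("training reduces the loss and reconstructs low-rank data", {
  h <- small_vae()$loss_history
  expect_lt(h$loss[10], h$loss[1])

  # near-noiseless rank-1 data: reconstruction should be accurate
  g <- generate_matrix(n_samples = 120, n_features = 20, latent_rank = 1,
                       noise_sd = 0.01, seed = 31)
  fit <- vae(g$matrix, hidden_dims = 8, latent_dim = 2,
             learning_rate = 2e-3, batch_size = 40, epochs = 150, seed = 31)
  xs <- apply_scaler(g$matrix, fit$scaler)$values
  recon <- decode(fit, encode(fit, xs)$mu)$mu
  rmse <- sqrt(mean((recon - xs)^2))
  expect_lt(rmse, 0.2)
})

test_that("vae validates its inputs", {
  g <- generate_matrix(30, 10, 2, 0.2, seed = 1)
  expect_error(vae(g$matrix, latent_dim = 10, hidden_dims = 8, epochs = 1),
               "latent_dim")
  withNA <- g$matrix
  withNA$values[1, 1] <- NA
  withNA$mask[1, 1] <- FALSE
  expect_error(vae(withNA, epochs = 1), "fully observed")
  expect_error(vae(g$matrix, hidden_dims = integer(0), epochs = 1),
               "hidden")
  expect_error(vae(g$matrix, hidden_dims = 8, latent_dim = 2, beta = -1,
                   epochs = 1), "beta")
})

test_that("model methods expose the fit: print, summary, coef, predict, simulate", {
  fit <- small_vae()
  expect_output(print(fit), "beta-VAE")
  s <- summary(fit)
  expect_gt(s$n_parameters, 0)
  expect_output(print(s), "parameters")
  expect_true(is.list(coef(fit)))
  expect_true(all(c("enc_Wmu", "dec_Wmu") %in% names(coef(fit))))

  pred <- predict(fit)
  expect_identical(dim(pred), dim(fit$data$values))
  lat <- predict(fit, type = "latent")
  expect_identical(ncol(lat), fit$config$latent_dim)
  res <- residuals(fit)
  expect_equal(res, fit$data$values - pred)

  sim <- simulate(fit, nsim = 5, seed = 1)
  expect_identical(dim(sim), c(5L, fit$config$input_dim))
  sim2 <- simulate(fit, nsim = 5, seed = 1)
  expect_identical(sim$values, sim2$values)
})

test_that("checkpoints round-trip through JSON with full precision", {
  fit <- small_vae()
  path <- withr::local_tempfile(fileext = ".json")
  save_vae(fit, path)
  back <- load_vae(path)
  x <- apply_scaler(fit$data, fit$scaler)$values[1:4, ]
  expect_equal(encode(back, x)$mu, encode(fit, x)$mu, tolerance = 1e-12)
  expect_identical(back$config$hidden_dims, fit$config$hidden_dims)
  expect_equal(back$scaler$mean, fit$scaler$mean)
})
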