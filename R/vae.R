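#' Fit a beta-variational auto-encoder to a complete omics matrix
#'
#' Trains a Gaussian VAE on fully observed samples: a ReLU multilayer
#' encoder maps each sample to the mean and log-variance of a diagonal
#' Gaussian approximate posterior `Q(z|x) = N(mu_z, diag(sigma_z^2))`; a
#' mirrored decoder maps latent codes to the mean and log-variance of the
#' reconstruction likelihood `P(x|z) = N(mu_x, diag(sigma_x^2))`. The loss
#' is the negative evidence lower bound with a `beta`-weighted KL term,
#'
#' \deqn{L = -E_q[\log P(x|z)] + \beta \, D_{KL}(Q(z|x) \| N(0, I)),}
#'
#' optimised with Adam via the reparameterization trick
#' `z = mu_z + sigma_z * eps`. `beta = 1` is the vanilla VAE; `beta = 0`
#' keeps the latent noise injection but removes latent regularization;
#' `beta > 1` enforces a smoother, more disentangled latent space.
#'
#' With `shift_lambda = c != 0` the observed training data are modelled as
#' `N(mu_x + c * sigma_x, sigma_x)`: the decoder mean then targets a
#' distribution shifted `c` standard deviations *below* the observed one,
#' which corrects the systematic over-estimation that occurs when missing
#' values are concentrated at the low end of the data (see
#' [select_shift_lambda()]).
#'
#' Input values are z-scored per feature before training (statistics kept
#' on the model and reused verbatim for any new data), since the model
#' assumes approximately standard-Gaussian features.
#'
#' @param x an [omics_matrix()] or numeric matrix, samples in rows, fully
#'   observed.
#' @param hidden_dims integer vector of encoder hidden-layer widths; the
#'   decoder mirrors them in reverse. Default `c(64, 32)`, a desk-scale
#'   architecture; cohort-scale runs use wider layers (e.g.
#'   `c(6000, 2000)` with `latent_dim = 200` for ~17k genes).
#' @param latent_dim latent-space dimension (default 8); must be smaller
#'   than the input dimension.
#' @param beta KL weight, `>= 0` (default 1).
#' @param shift_lambda shift-correction multiplier, in units of the
#'   decoder standard deviation (default 0 = standard VAE).
#' @param learning_rate Adam step size (default `5e-5`, the cohort-scale
#'   setting; small dense problems train faster at `1e-3`).
#' @param batch_size minibatch size (default 250).
#' @param epochs training epochs (default 250).
#' @param seed integer seed governing initialisation, shuffling and the
#'   latent noise draws.
#' @param learn_decoder_var if `TRUE` (default) the decoder outputs a
#'   learned per-feature log-variance; if `FALSE` it is frozen at 0, so
#'   the reconstruction term is the plain squared error (up to the
#'   Gaussian normaliser) and `shift_lambda` shifts in raw sd units.
#' @param scale z-score internally (default `TRUE`). With `FALSE` the
#'   input is assumed already scaled and an identity scaler is stored.
#' @param keep_data retain the training matrix on the object (needed by
#'   [residuals.vae()]); default `TRUE`.
#' @param logvar_clamp symmetric clamp on all log-variance outputs
#'   (default 10) guarding numeric overflow.
#' @param verbose print the loss every 10 epochs.
#'
#' @return An object of class `vae`: list with `params` (weights),
#'   `config`, `scaler` ([fit_scaler()] statistics), `loss_history`
#'   (per-epoch total / reconstruction / KL), and `data` (if kept).
#'   Supports `print`, `summary`, `coef`, `plot`, `predict`, `simulate`
#'   and `residuals`.
#' @seealso [impute_vae()] for filling missing values with a fitted
#'   model, [elbo_loss()] for evaluating the objective.
#' @examples
#' g <- generate_matrix(n_samples = 60, n_features = 30, latent_rank = 2, seed = 1)
#' fit <- vae(g$matrix, hidden_dims = 8, latent_dim = 2, epochs = 20,
#'            learning_rate = 1e-3, batch_size = 32, seed = 1)
#' fit
#' @export
vae <- function(x,
                hidden_dims = c(64, 32),
                latent_dim = 8,
                beta = 1,
                shift_lambda = 0,
                learning_rate = 5e-5,
                batch_size = 250,
                epochs = 250,
                seed = 1,
                learn_decoder_var = TRUE,
                scale = TRUE,
                keep_data = TRUE,
                logvar_clamp = 10,
                verbose = FALSE) {
  m <- as_omics(x)
  if (any(!m$mask))
    stop("training data must be fully observed; impute or drop features first")
  p <- ncol(m$values)
  if (latent_dim >= p) stop("latent_dim must be smaller than the input dimension")
  if (length(hidden_dims) < 1 || any(hidden_dims < 1))
    stop("at least one positive hidden dimension is required")
  if (beta < 0) stop("beta must be non-negative")
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)

  if (scale) {
    scaler <- fit_scaler(m)
  } else {
    scaler <- structure(list(mean = rep(0, p), sd = rep(1, p),
                             feature_ids = m$feature_ids),
                        class = "scaler_stats")
  }
  X <- apply_scaler(m, scaler)$values
  cfg <- list(input_dim = p, hidden_dims = as.integer(hidden_dims),
              latent_dim = as.integer(latent_dim), beta = beta,
              shift_lambda = shift_lambda, learning_rate = learning_rate,
              batch_size = as.integer(batch_size), epochs = as.integer(epochs),
              seed = as.integer(seed), learn_decoder_var = learn_decoder_var,
              logvar_clamp = logvar_clamp, feature_ids = m$feature_ids)

  fitted <- with_seed(seed, vae_train_loop(X, cfg, verbose))

  structure(list(params = fitted$params, config = cfg, scaler = scaler,
                 loss_history = fitted$history,
                 data = if (keep_data) m else NULL,
                 call = match.call()),
            class = "vae")
}

# ---- parameter initialisation -------------------------------------------

vae_init_params <- function(cfg) {
  he <- function(n_in, n_out, gain = sqrt(2)) {
    matrix(stats::rnorm(n_in * n_out, sd = gain / sqrt(n_in)), n_in, n_out)
  }
  pm <- list()
  enc_dims <- c(cfg$input_dim, cfg$hidden_dims)
  for (l in seq_along(cfg$hidden_dims)) {
    pm[[paste0("enc_W", l)]] <- he(enc_dims[l], enc_dims[l + 1])
    pm[[paste0("enc_b", l)]] <- rep(0, enc_dims[l + 1])
  }
  hk <- utils::tail(enc_dims, 1)
  pm$enc_Wmu <- he(hk, cfg$latent_dim, gain = 1)
  pm$enc_bmu <- rep(0, cfg$latent_dim)
  pm$enc_Wlv <- he(hk, cfg$latent_dim, gain = 0.1)
  pm$enc_blv <- rep(0, cfg$latent_dim)

  dec_hidden <- rev(cfg$hidden_dims)
  dec_dims <- c(cfg$latent_dim, dec_hidden)
  for (l in seq_along(dec_hidden)) {
    pm[[paste0("dec_W", l)]] <- he(dec_dims[l], dec_dims[l + 1])
    pm[[paste0("dec_b", l)]] <- rep(0, dec_dims[l + 1])
  }
  gk <- utils::tail(dec_dims, 1)
  pm$dec_Wmu <- he(gk, cfg$input_dim, gain = 1)
  pm$dec_bmu <- rep(0, cfg$input_dim)
  if (cfg$learn_decoder_var) {
    pm$dec_Wlv <- he(gk, cfg$input_dim, gain = 0.1)
    pm$dec_blv <- rep(0, cfg$input_dim)
  }
  pm
}

addbias <- function(M, b) sweep(M, 2, b, "+")
clampv <- function(M, c) pmin(pmax(M, -c), c)

# ---- forward pass --------------------------------------------------------

vae_forward <- function(pm, X, eps, cfg) {
  L <- length(cfg$hidden_dims)
  Aenc <- Henc <- vector("list", L)
  H <- X
  for (l in seq_len(L)) {
    Aenc[[l]] <- addbias(H %*% pm[[paste0("enc_W", l)]], pm[[paste0("enc_b", l)]])
    H <- Henc[[l]] <- pmax(Aenc[[l]], 0)
  }
  mu_z <- addbias(H %*% pm$enc_Wmu, pm$enc_bmu)
  lvz_raw <- addbias(H %*% pm$enc_Wlv, pm$enc_blv)
  lv_z <- clampv(lvz_raw, cfg$logvar_clamp)
  z <- mu_z + exp(0.5 * lv_z) * eps

  Adec <- Hdec <- vector("list", L)
  G <- z
  for (l in seq_len(L)) {
    Adec[[l]] <- addbias(G %*% pm[[paste0("dec_W", l)]], pm[[paste0("dec_b", l)]])
    G <- Hdec[[l]] <- pmax(Adec[[l]], 0)
  }
  mu_x <- addbias(G %*% pm$dec_Wmu, pm$dec_bmu)
  if (cfg$learn_decoder_var) {
    lvx_raw <- addbias(G %*% pm$dec_Wlv, pm$dec_blv)
    lv_x <- clampv(lvx_raw, cfg$logvar_clamp)
  } else {
    lvx_raw <- lv_x <- matrix(0, nrow(X), cfg$input_dim)
  }
  list(Aenc = Aenc, Henc = Henc, mu_z = mu_z, lvz_raw = lvz_raw, lv_z = lv_z,
       eps = eps, z = z, Adec = Adec, Hdec = Hdec, mu_x = mu_x,
       lvx_raw = lvx_raw, lv_x = lv_x)
}

# loss components from a forward cache; per-sample vectors
vae_loss_terms <- function(fw, X, shift_lambda) {
  s <- exp(0.5 * fw$lv_x)
  v <- s * s
  R <- X - (fw$mu_x + shift_lambda * s)
  recon <- 0.5 * rowSums(log(2 * pi) + fw$lv_x + R * R / v)
  kl <- 0.5 * rowSums(fw$mu_z^2 + exp(fw$lv_z) - 1 - fw$lv_z)
  list(recon = recon, kl = kl, R = R, s = s, v = v)
}

# ---- backward pass -------------------------------------------------------

vae_backward <- function(pm, fw, X, cfg, beta, shift_lambda, terms) {
  B <- nrow(X)
  L <- length(cfg$hidden_dims)
  g <- list()

  dmu_x <- -(terms$R / terms$v) / B
  if (cfg$learn_decoder_var) {
    gate_x <- abs(fw$lvx_raw) < cfg$logvar_clamp
    dlv_x <- (0.5 * (1 - terms$R^2 / terms$v -
                       shift_lambda * terms$R / terms$s) / B) * gate_x
  }

  Gk <- if (L > 0) fw$Hdec[[L]] else fw$z
  g$dec_Wmu <- crossprod(Gk, dmu_x)
  g$dec_bmu <- colSums(dmu_x)
  delta <- dmu_x %*% t(pm$dec_Wmu)
  if (cfg$learn_decoder_var) {
    g$dec_Wlv <- crossprod(Gk, dlv_x)
    g$dec_blv <- colSums(dlv_x)
    delta <- delta + dlv_x %*% t(pm$dec_Wlv)
  }
  for (l in rev(seq_len(L))) {
    dA <- delta * (fw$Adec[[l]] > 0)
    inp <- if (l == 1) fw$z else fw$Hdec[[l - 1]]
    g[[paste0("dec_W", l)]] <- crossprod(inp, dA)
    g[[paste0("dec_b", l)]] <- colSums(dA)
    delta <- dA %*% t(pm[[paste0("dec_W", l)]])
  }
  dz <- delta

  dmu_z <- dz + (beta / B) * fw$mu_z
  gate_z <- abs(fw$lvz_raw) < cfg$logvar_clamp
  dlv_z <- (dz * fw$eps * 0.5 * exp(0.5 * fw$lv_z) +
              (beta / B) * 0.5 * (exp(fw$lv_z) - 1)) * gate_z

  Hk <- if (L > 0) fw$Henc[[L]] else X
  g$enc_Wmu <- crossprod(Hk, dmu_z)
  g$enc_bmu <- colSums(dmu_z)
  g$enc_Wlv <- crossprod(Hk, dlv_z)
  g$enc_blv <- colSums(dlv_z)
  delta <- dmu_z %*% t(pm$enc_Wmu) + dlv_z %*% t(pm$enc_Wlv)
  for (l in rev(seq_len(L))) {
    dA <- delta * (fw$Aenc[[l]] > 0)
    inp <- if (l == 1) X else fw$Henc[[l - 1]]
    g[[paste0("enc_W", l)]] <- crossprod(inp, dA)
    g[[paste0("enc_b", l)]] <- colSums(dA)
    delta <- dA %*% t(pm[[paste0("enc_W", l)]])
  }
  g
}

# ---- Adam + training loop ------------------------------------------------

vae_train_loop <- function(X, cfg, verbose) {
  pm <- vae_init_params(cfg)
  mstate <- lapply(pm, function(p) p * 0)
  vstate <- lapply(pm, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps_adam <- 1e-8
  t_step <- 0
  n <- nrow(X)
  bs <- min(cfg$batch_size, n)
  history <- matrix(NA_real_, cfg$epochs, 3,
                    dimnames = list(NULL, c("loss", "recon", "kl")))

  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    ep_loss <- ep_recon <- ep_kl <- 0; ep_n <- 0
    for (start in seq(1, n, by = bs)) {
      rows <- perm[start:min(start + bs - 1, n)]
      Xb <- X[rows, , drop = FALSE]
      eps <- matrix(stats::rnorm(length(rows) * cfg$latent_dim),
                    length(rows), cfg$latent_dim)
      fw <- vae_forward(pm, Xb, eps, cfg)
      terms <- vae_loss_terms(fw, Xb, cfg$shift_lambda)
      loss <- mean(terms$recon) + cfg$beta * mean(terms$kl)
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d; lower the learning rate",
                     epoch))
      g <- vae_backward(pm, fw, Xb, cfg, cfg$beta, cfg$shift_lambda, terms)
      t_step <- t_step + 1
      corr1 <- 1 - b1^t_step
      corr2 <- 1 - b2^t_step
      for (nm in names(pm)) {
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g[[nm]]
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g[[nm]]^2
        pm[[nm]] <- pm[[nm]] - cfg$learning_rate *
          (mstate[[nm]] / corr1) / (sqrt(vstate[[nm]] / corr2) + eps_adam)
      }
      w <- length(rows)
      ep_loss <- ep_loss + loss * w
      ep_recon <- ep_recon + mean(terms$recon) * w
      ep_kl <- ep_kl + mean(terms$kl) * w
      ep_n <- ep_n + w
    }
    history[epoch, ] <- c(ep_loss, ep_recon, ep_kl) / ep_n
    if (verbose && (epoch %% 10 == 0 || epoch == 1))
      message(sprintf("epoch %4d  loss %10.4f  recon %10.4f  kl %8.4f",
                      epoch, history[epoch, 1], history[epoch, 2],
                      history[epoch, 3]))
  }
  list(params = pm,
       history = data.frame(epoch = seq_len(cfg$epochs), history))
}

# ---- exported building blocks -------------------------------------------

#' Encode samples to their approximate-posterior parameters
#'
#' Runs the encoder on already-scaled, fully numeric input and returns
#' the mean and log-variance of `Q(z|x)` for each sample. Deterministic
#' given the model parameters.
#'
#' @param model a fitted [vae()].
#' @param x numeric vector (one sample) or matrix in the model's scaled
#'   space; no missing values allowed — the imputation loop pre-fills.
#' @return list with matrices `mu` and `logvar`
#'   (`n_samples x latent_dim`).
#' @export
encode <- function(model, x) {
  stopifnot(inherits(model, "vae"))
  x <- rbind_vec(x, model$config$input_dim)
  if (anyNA(x)) stop("encode() requires fully numeric input; pre-fill missing values")
  fw <- vae_forward(model$params, x,
                    matrix(0, nrow(x), model$config$latent_dim), model$config)
  list(mu = fw$mu_z, logvar = fw$lv_z)
}

#' Decode latent codes to reconstruction-likelihood parameters
#'
#' @param model a fitted [vae()].
#' @param z numeric vector or matrix of latent codes.
#' @return list with matrices `mu` and `logvar`
#'   (`n_samples x input_dim`), in the model's scaled space.
#' @export
decode <- function(model, z) {
  stopifnot(inherits(model, "vae"))
  z <- rbind_vec(z, model$config$latent_dim)
  cfg <- model$config
  pm <- model$params
  L <- length(cfg$hidden_dims)
  G <- z
  for (l in seq_len(L))
    G <- pmax(addbias(G %*% pm[[paste0("dec_W", l)]], pm[[paste0("dec_b", l)]]), 0)
  mu <- addbias(G %*% pm$dec_Wmu, pm$dec_bmu)
  lv <- if (cfg$learn_decoder_var)
    clampv(addbias(G %*% pm$dec_Wlv, pm$dec_blv), cfg$logvar_clamp)
  else matrix(0, nrow(z), cfg$input_dim)
  list(mu = mu, logvar = lv)
}

rbind_vec <- function(x, d) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != d) stop(sprintf("expected %d columns, got %d", d, ncol(x)))
  x
}

#' Reparameterization trick
#'
#' Maps posterior parameters and external standard-normal noise to a
#' latent draw `z = mu + exp(logvar / 2) * eps`, keeping the stochasticity
#' outside the parameters so gradients flow through `mu` and `logvar`.
#'
#' @param mu,logvar posterior mean and log-variance (vectors or matrices
#'   of equal shape).
#' @param eps standard-normal noise of the same shape.
#' @return The latent sample(s), same shape as `mu`.
#' @export
reparameterize <- function(mu, logvar, eps) {
  stopifnot(length(mu) == length(logvar), length(mu) == length(eps))
  mu + exp(0.5 * logvar) * eps
}

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' Closed form `0.5 * sum(mu^2 + exp(logvar) - 1 - logvar)`, the latent
#' regularizer of the ELBO. Always non-negative.
#'
#' @param mu,logvar posterior parameters; vectors (one sample, returns a
#'   scalar) or matrices (returns one value per row).
#' @return Non-negative KL divergence(s) in nats.
#' @export
kl_divergence <- function(mu, logvar) {
  if (is.null(dim(mu))) {
    0.5 * sum(mu^2 + exp(logvar) - 1 - logvar)
  } else {
    0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar)
  }
}

#' Shift-corrected Gaussian reconstruction negative log-likelihood
#'
#' Negative log-density of `x` under
#' `N(mu + shift_lambda * sigma, sigma^2)` with
#' `sigma = exp(logvar / 2)`, summed over features. `shift_lambda = 0`
#' recovers the standard VAE reconstruction term; a positive value models
#' observed data as sitting `shift_lambda` standard deviations above the
#' decoder mean, so the mean itself targets lower (missing-like) values.
#'
#' @param x data (vector or matrix, scaled space).
#' @param mu,logvar decoder outputs, same shape as `x`.
#' @param shift_lambda shift multiplier (default 0).
#' @return Per-sample NLL (scalar for vector input).
#' @export
reconstruction_nll <- function(x, mu, logvar, shift_lambda = 0) {
  stopifnot(length(x) == length(mu), length(x) == length(logvar))
  s <- exp(0.5 * logvar)
  r <- x - (mu + shift_lambda * s)
  nll <- 0.5 * (log(2 * pi) + logvar + r * r / (s * s))
  if (is.null(dim(x))) sum(nll) else rowSums(nll)
}

#' Evaluate the beta-VAE objective on a batch
#'
#' Runs one forward pass and returns the batch-mean loss
#' `mean(reconstruction NLL) + beta * mean(KL)`, with the two components.
#' Supplying `eps` makes the evaluation fully deterministic; `eps = NULL`
#' draws fresh standard-normal noise.
#'
#' @param model a fitted [vae()].
#' @param x batch in the model's scaled space (vector or matrix).
#' @param beta,shift_lambda override the model's settings (default: use
#'   the fitted values).
#' @param eps optional noise matrix (`n x latent_dim`).
#' @return list with `loss`, `recon`, `kl` (batch means).
#' @export
elbo_loss <- function(model, x, beta = model$config$beta,
                      shift_lambda = model$config$shift_lambda, eps = NULL) {
  stopifnot(inherits(model, "vae"))
  x <- rbind_vec(x, model$config$input_dim)
  if (is.null(eps))
    eps <- matrix(stats::rnorm(nrow(x) * model$config$latent_dim),
                  nrow(x), model$config$latent_dim)
  fw <- vae_forward(model$params, x, eps, model$config)
  terms <- vae_loss_terms(fw, x, shift_lambda)
  list(loss = mean(terms$recon) + beta * mean(terms$kl),
       recon = mean(terms$recon), kl = mean(terms$kl))
}

# ---- S3 methods ----------------------------------------------------------

#' @export
print.vae <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("beta-VAE: %d -> [%s] -> %d -> [%s] -> %d\n",
              cfg$input_dim, paste(cfg$hidden_dims, collapse = ", "),
              cfg$latent_dim, paste(rev(cfg$hidden_dims), collapse = ", "),
              cfg$input_dim))
  cat(sprintf("  beta = %g, shift_lambda = %g, %s decoder variance\n",
              cfg$beta, cfg$shift_lambda,
              if (cfg$learn_decoder_var) "learned" else "unit"))
  cat(sprintf("  trained %d epochs (lr %g, batch %d); final loss %.4f\n",
              cfg$epochs, cfg$learning_rate, cfg$batch_size,
              utils::tail(x$loss_history$loss, 1)))
  invisible(x)
}

#' @export
summary.vae <- function(object, ...) {
  h <- object$loss_history
  n_par <- sum(vapply(object$params, length, 1L))
  out <- list(config = object$config, n_parameters = n_par,
              first_loss = h$loss[1], final_loss = utils::tail(h$loss, 1),
              final_recon = utils::tail(h$recon, 1),
              final_kl = utils::tail(h$kl, 1))
  class(out) <- "summary.vae"
  out
}

#' @export
print.summary.vae <- function(x, ...) {
  cat(sprintf("beta-VAE with %d parameters\n", x$n_parameters))
  cat(sprintf("  loss: %.4f (epoch 1) -> %.4f (final); recon %.4f, kl %.4f\n",
              x$first_loss, x$final_loss, x$final_recon, x$final_kl))
  invisible(x)
}

#' @export
coef.vae <- function(object, ...) object$params

#' Plot the training loss history of a VAE
#'
#' @param x a fitted [vae()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.vae <- function(x, ...) {
  h <- x$loss_history
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "loss (NLL + beta*KL)", ...)
  graphics::lines(h$epoch, h$recon, lty = 2)
  graphics::legend("topright", legend = c("total", "reconstruction"),
                   lty = c(1, 2), bty = "n")
  invisible(h)
}

#' Deterministic reconstruction or latent embedding of new samples
#'
#' Encodes each (fully observed) sample to its posterior mean and, for
#' `type = "response"`, decodes that mean back to the reconstruction mean
#' on the original data scale.
#'
#' @param object a fitted [vae()].
#' @param newdata an [omics_matrix()] or numeric matrix on the raw data
#'   scale; defaults to the training data.
#' @param type `"response"` (reconstruction, raw scale) or `"latent"`
#'   (posterior means).
#' @param ... ignored.
#' @return A numeric matrix.
#' @export
predict.vae <- function(object, newdata = NULL,
                        type = c("response", "latent"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (is.null(object$data)) stop("model was fitted with keep_data = FALSE; supply newdata")
    newdata <- object$data
  }
  m <- as_omics(newdata)
  if (any(!m$mask))
    stop("newdata has missing values; use impute_vae() for imputation")
  xs <- apply_scaler(m, object$scaler)$values
  enc <- encode(object, xs)
  if (type == "latent") {
    rownames(enc$mu) <- m$sample_ids
    return(enc$mu)
  }
  dec <- decode(object, enc$mu)
  out <- sweep(sweep(dec$mu, 2, object$scaler$sd, "*"), 2,
               object$scaler$mean, "+")
  dimnames(out) <- dimnames(m$values)
  out
}

#' Sample new data from the fitted generative model
#'
#' Draws `z ~ N(0, I)`, decodes, and samples observed-like data from
#' `N(mu + shift_lambda * sigma, sigma^2)`, returned on the raw scale.
#'
#' @param object a fitted [vae()].
#' @param nsim number of samples to generate.
#' @param seed integer seed (optional).
#' @param ... ignored.
#' @return An [omics_matrix()] of `nsim` generated samples.
#' @export
simulate.vae <- function(object, nsim = 1, seed = NULL, ...) {
  cfg <- object$config
  draw <- function() {
    z <- matrix(stats::rnorm(nsim * cfg$latent_dim), nsim, cfg$latent_dim)
    dec <- decode(object, z)
    s <- exp(0.5 * dec$logvar)
    dec$mu + cfg$shift_lambda * s +
      s * matrix(stats::rnorm(nsim * cfg$input_dim), nsim, cfg$input_dim)
  }
  xs <- if (is.null(seed)) draw() else with_seed(seed, draw())
  raw <- sweep(sweep(xs, 2, object$scaler$sd, "*"), 2, object$scaler$mean, "+")
  colnames(raw) <- cfg$feature_ids
  omics_matrix(raw)
}

#' @export
residuals.vae <- function(object, ...) {
  if (is.null(object$data))
    stop("model was fitted with keep_data = FALSE; residuals unavailable")
  object$data$values - predict(object, object$data)
}
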