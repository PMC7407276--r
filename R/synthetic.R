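#' Generate a correlated low-rank synthetic omics matrix
#'
#' Draws `X = Z W + noise` from a linear-Gaussian factor model:
#' `Z` is `n_samples x latent_rank` standard normal, the loadings `W` are
#' scaled so each feature has roughly unit signal variance, and the noise
#' is i.i.d. `N(0, noise_sd^2)`. After z-scoring such a matrix is
#' approximately standard Gaussian with strong cross-feature correlation —
#' the structure that makes nearest-neighbour, SVD and auto-encoder
#' imputation informative in real transcriptome/methylome cohorts.
#'
#' @param n_samples,n_features matrix dimensions.
#' @param latent_rank number of latent factors; must not exceed
#'   `min(n_samples, n_features)`.
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (default 0.3, a clearly sub-dominant noise floor).
#' @param seed integer seed; output is a pure function of the arguments.
#' @param modality stored on the returned matrix.
#' @return A list: `matrix` (an [omics_matrix()], fully observed),
#'   `factors` (the true `Z`, for recovery tests), `loadings` (`W`).
#' @examples
#' g <- generate_matrix(n_samples = 40, n_features = 20, latent_rank = 3, seed = 1)
#' dim(g$matrix)
#' @export
generate_matrix <- function(n_samples = 300, n_features = 500,
                            latent_rank = 10, noise_sd = 0.3, seed = 1,
                            modality = "generic") {
  if (latent_rank > min(n_samples, n_features))
    stop("latent_rank exceeds min(n_samples, n_features)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  out <- with_seed(seed, {
    z <- matrix(stats::rnorm(n_samples * latent_rank), n_samples, latent_rank)
    w <- matrix(stats::rnorm(latent_rank * n_features, sd = 1 / sqrt(latent_rank)),
                latent_rank, n_features)
    b <- stats::rnorm(n_features, sd = 0.5)
    eps <- if (noise_sd > 0)
      matrix(stats::rnorm(n_samples * n_features, sd = noise_sd),
             n_samples, n_features)
    else 0
    list(z = z, w = w, x = z %*% w + matrix(b, n_samples, n_features,
                                            byrow = TRUE) + eps)
  })
  list(matrix = omics_matrix(out$x, modality = modality),
       factors = out$z, loadings = out$w)
}

#' Generate per-feature covariates driving MNAR mechanisms
#'
#' Produces the feature-level annotations that the not-at-random masking
#' mechanisms condition on: GC content (uniform on \[0.2, 0.8\]), read
#' coverage (negative-binomial counts), and each feature's baseline level
#' (its mean in the supplied matrix). `corr_with_mean` tilts coverage
#' towards high-baseline features, emulating expression-dependent
#' sequencing depth.
#'
#' @param m an [omics_matrix()] supplying `n_features` and baselines.
#' @param corr_with_mean target correlation in \[-1, 1\] between coverage
#'   and baseline level (0 = independent).
#' @param coverage_mean mean of the coverage distribution (reads).
#' @param coverage_size negative-binomial size (dispersion) parameter.
#' @param seed integer seed.
#' @return A `feature_covariates` list: `gc_content`, `coverage`,
#'   `baseline_level`, all length `n_features`.
#' @export
generate_feature_covariates <- function(m, corr_with_mean = 0,
                                        coverage_mean = 10,
                                        coverage_size = 2, seed = 1) {
  stopifnot(is_omics_matrix(m))
  if (abs(corr_with_mean) > 1) stop("|corr_with_mean| must be <= 1")
  p <- ncol(m$values)
  baseline <- colMeans(m$values, na.rm = TRUE)
  out <- with_seed(seed, {
    gc <- stats::runif(p, 0.2, 0.8)
    # Gaussian copula: blend a baseline-rank component into the latent
    # normal before mapping through the NB quantile function
    u <- stats::rnorm(p)
    if (corr_with_mean != 0) {
      zb <- stats::qnorm(rank(baseline, ties.method = "average") / (p + 1))
      u <- corr_with_mean * zb + sqrt(1 - corr_with_mean^2) * u
    }
    cov <- stats::qnbinom(stats::pnorm(u), size = coverage_size,
                          mu = coverage_mean)
    list(gc = gc, cov = cov)
  })
  structure(list(gc_content = out$gc, coverage = as.integer(out$cov),
                 baseline_level = unname(baseline)),
            class = "feature_covariates")
}

#' Generate clinical variables correlated with the first latent factor
#'
#' Builds a per-sample clinical table of the kind used to judge whether
#' imputation preserves downstream associations: an ordinal tumour grade
#' in \{2, 3, 4\} cut from a noisy linear score on the first latent
#' factor, and an exponential survival time with log-hazard
#' `effect_size * Z1`, censored completely at random at `censor_rate`.
#'
#' @param factors latent factor matrix from [generate_matrix()]; the first
#'   column drives both outcomes.
#' @param effect_size linear effect of the factor on the grade score and
#'   the log-hazard (0 = no association).
#' @param censor_rate probability an observation is censored, in \[0, 1).
#' @param seed integer seed.
#' @param baseline_hazard events per month at `Z1 = 0` (default 0.02,
#'   i.e. a 50-month median scale).
#' @return A data.frame with columns `grade` (integer 2/3/4),
#'   `survival_time` (months, > 0), `event` (logical).
#' @export
generate_clinical <- function(factors, effect_size = 1, censor_rate = 0.2,
                              seed = 1, baseline_hazard = 0.02) {
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  z1 <- as.matrix(factors)[, 1]
  n <- length(z1)
  with_seed(seed, {
    score <- effect_size * z1 + stats::rnorm(n)
    grade <- as.integer(cut(score, breaks = stats::quantile(
      score, c(0, 1 / 3, 2 / 3, 1)), labels = FALSE, include.lowest = TRUE)) + 1L
    hazard <- baseline_hazard * exp(effect_size * z1)
    time <- stats::rexp(n, rate = hazard)
    event <- stats::runif(n) >= censor_rate
    # censored subjects observed for a uniform fraction of their true time
    time[!event] <- time[!event] * stats::runif(sum(!event))
    time <- pmax(time, .Machine$double.eps)
    data.frame(grade = grade, survival_time = time, event = event)
  })
}
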