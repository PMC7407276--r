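# Delimited-text interchange: matrices carry sample IDs in the first
# column and feature IDs in the header; missing entries are the literal
# "NA". TSV is the default everywhere.

#' Read / write an omics matrix as delimited text
#'
#' @param path file path.
#' @param delim field delimiter (default tab).
#' @param modality stored on the returned matrix.
#' @return `read_omics_matrix` returns an [omics_matrix()];
#'   `write_omics_matrix` returns `path` invisibly.
#' @export
read_omics_matrix <- function(path, delim = "\t", modality = "generic") {
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, row.names = 1,
                          na.strings = "NA", comment.char = "")
  omics_matrix(as.matrix(df), modality = modality)
}

#' @rdname read_omics_matrix
#' @param m an [omics_matrix()].
#' @export
write_omics_matrix <- function(m, path, delim = "\t") {
  stopifnot(is_omics_matrix(m))
  df <- data.frame(sample_id = m$sample_ids, m$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = delim, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read / write z-scoring statistics as delimited text
#'
#' Three columns: `feature_id`, `mean`, `sd`.
#'
#' @param s a `scaler_stats` object.
#' @param path file path.
#' @param delim field delimiter.
#' @return `read_scaler` returns a `scaler_stats`; `write_scaler` the
#'   path, invisibly.
#' @export
write_scaler <- function(s, path, delim = "\t") {
  stopifnot(inherits(s, "scaler_stats"))
  utils::write.table(
    data.frame(feature_id = s$feature_ids, mean = s$mean, sd = s$sd),
    path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path, delim = "\t") {
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE)
  structure(list(mean = df$mean, sd = df$sd,
                 feature_ids = as.character(df$feature_id)),
            class = "scaler_stats")
}

#' Write / read a masking trial's ground truth
#'
#' The corrupted matrix is written with [write_omics_matrix()]; the
#' removed values go to a three-column table (`sample_id`, `feature_id`,
#' `true_value`).
#'
#' @param trial a `masked_trial`.
#' @param matrix_path,truth_path output paths.
#' @param delim field delimiter.
#' @return Invisibly, the two paths.
#' @export
write_masked_trial <- function(trial, matrix_path, truth_path, delim = "\t") {
  stopifnot(inherits(trial, "masked_trial"))
  write_omics_matrix(trial$corrupted, matrix_path, delim)
  m <- trial$corrupted
  utils::write.table(
    data.frame(sample_id = m$sample_ids[trial$masked_index[, 1]],
               feature_id = m$feature_ids[trial$masked_index[, 2]],
               true_value = trial$truth),
    truth_path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, truth_path))
}

#' @rdname write_masked_trial
#' @param corrupted the corrupted [omics_matrix()] the truth refers to.
#' @param path the truth table path.
#' @return `read_masked_trial` rebuilds the `masked_trial`.
#' @export
read_masked_trial <- function(corrupted, path, delim = "\t") {
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE)
  i <- match(as.character(df$sample_id), corrupted$sample_ids)
  j <- match(as.character(df$feature_id), corrupted$feature_ids)
  if (anyNA(i) || anyNA(j))
    stop("truth table refers to samples/features absent from the matrix")
  structure(list(corrupted = corrupted, truth = df$true_value,
                 masked_index = cbind(sample = i, feature = j),
                 mechanism = "file", seed = NA_integer_),
            class = "masked_trial")
}

#' Save / load a fitted VAE as a JSON checkpoint
#'
#' The checkpoint stores the architecture configuration, all weights at
#' full precision, the z-scoring statistics and the loss history, so a
#' model can be trained once and reused for imputation elsewhere.
#'
#' @param model a fitted [vae()].
#' @param path checkpoint path (JSON).
#' @return `save_vae` returns the path invisibly; `load_vae` the
#'   reconstructed `vae` object (without training data, so
#'   [residuals.vae()] is unavailable on it).
#' @export
save_vae <- function(model, path) {
  stopifnot(inherits(model, "vae"))
  payload <- list(
    format = "vaeimpute-checkpoint-1",
    config = model$config[setdiff(names(model$config), "feature_ids")],
    feature_ids = model$config$feature_ids,
    scaler = list(mean = model$scaler$mean, sd = model$scaler$sd,
                  feature_ids = model$scaler$feature_ids),
    params = model$params,
    loss_history = model$loss_history)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_vae
#' @export
load_vae <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "vaeimpute-checkpoint-1"))
    stop("not a vaeimpute checkpoint")
  cfg <- payload$config
  cfg$feature_ids <- payload$feature_ids
  params <- lapply(payload$params, function(p) {
    if (is.matrix(p)) p else as.numeric(p)
  })
  structure(list(params = params, config = cfg,
                 scaler = structure(payload$scaler, class = "scaler_stats"),
                 loss_history = as.data.frame(payload$loss_history),
                 data = NULL, call = NULL),
            class = "vae")
}
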