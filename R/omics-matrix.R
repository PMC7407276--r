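#' Sample-by-feature omics matrix with an explicit missingness mask
#'
#' The central data container: a numeric matrix with samples as rows and
#' features (genes or CpG sites) as columns, paired with a logical mask of
#' the same shape. The mask is authoritative: `TRUE` marks an observed
#' entry, `FALSE` a missing one, and missing entries always hold `NA` in
#' `values`.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#'   `NA` entries are taken as missing unless `mask` says otherwise.
#' @param mask logical matrix of the same shape; `TRUE` = observed.
#'   Defaults to `!is.na(values)`.
#' @param sample_ids,feature_ids character vectors of unique identifiers;
#'   default to dimnames or `S1..Sn` / `F1..Fp`.
#' @param modality one of `"expression"`, `"methylation"`, `"generic"`;
#'   gates which normalising transform applies.
#'
#' @return An object of class `omics_matrix`: a list with elements
#'   `values`, `mask`, `sample_ids`, `feature_ids`, `modality`.
#' @examples
#' m <- omics_matrix(matrix(c(1, NA, 3, 4), 2, 2))
#' m$mask
#' @export
omics_matrix <- function(values,
                         mask = NULL,
                         sample_ids = NULL,
                         feature_ids = NULL,
                         modality = c("generic", "expression", "methylation")) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  if (!is.logical(mask)) stop("`mask` must be a logical matrix")
  if (!identical(dim(values), dim(mask)))
    stop("`values` and `mask` must have identical dimensions")
  if (anyNA(mask)) stop("`mask` may not contain NA")
  if (any(is.na(values) & mask))
    stop("entries flagged observed in `mask` may not be NA in `values`")
  values[!mask] <- NA_real_

  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- colnames(values)
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values) || anyDuplicated(sample_ids))
    stop("`sample_ids` must be unique and match the number of rows")
  if (length(feature_ids) != ncol(values) || anyDuplicated(feature_ids))
    stop("`feature_ids` must be unique and match the number of columns")
  dimnames(values) <- dimnames(mask) <- list(sample_ids, feature_ids)

  structure(
    list(values = values, mask = mask, sample_ids = sample_ids,
         feature_ids = feature_ids, modality = modality),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  n_miss <- sum(!x$mask)
  cat(sprintf("omics_matrix (%s): %d samples x %d features, %d missing (%.1f%%)\n",
              x$modality, nrow(x$values), ncol(x$values), n_miss,
              100 * n_miss / length(x$mask)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' @export
as.matrix.omics_matrix <- function(x, ...) x$values

is_omics_matrix <- function(x) inherits(x, "omics_matrix")

# coerce plain matrices on the way into the imputers / transforms
as_omics <- function(x, modality = "generic") {
  if (is_omics_matrix(x)) x else omics_matrix(x, modality = modality)
}

# rebuild an omics_matrix with new values, keeping ids; mask recomputed
# from NA pattern unless given
replace_values <- function(m, values, mask = NULL) {
  omics_matrix(values, mask = mask, sample_ids = m$sample_ids,
               feature_ids = m$feature_ids, modality = m$modality)
}

#' Subset an omics matrix by samples and/or features
#'
#' @param x an [omics_matrix()].
#' @param i,j sample / feature indices (integer, logical or character).
#' @param ... ignored.
#' @return An `omics_matrix` restricted to the selected rows/columns.
#' @export
`[.omics_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  omics_matrix(x$values[i, j, drop = FALSE],
               mask = x$mask[i, j, drop = FALSE],
               modality = x$modality)
}
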