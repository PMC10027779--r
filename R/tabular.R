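#' Restrict an expression matrix to a landmark gene panel
#'
#' Retains the intersection of the matrix genes (rows) with a landmark gene
#' list — typically the 942-gene LINCS landmark panel, which captures most
#' transcriptome-wide expression variation — in landmark-list order.
#'
#' @param mat numeric matrix, genes in rows (rownames are gene IDs),
#'   specimens in columns.
#' @param landmark_list character vector of gene IDs to retain.
#' @return the filtered matrix, rows ordered as in `landmark_list`.
#'   Genes of the list missing from the matrix are dropped with a warning.
#' @export
filter_landmark_genes <- function(mat, landmark_list) {
  if (length(landmark_list) == 0L)
    abort_validation("`landmark_list` must be non-empty")
  if (is.null(rownames(mat)))
    abort_validation("expression matrix must have gene IDs as rownames")
  keep <- landmark_list[landmark_list %in% rownames(mat)]
  if (length(keep) == 0L)
    abort_validation("no landmark genes found in the expression matrix")
  missing <- setdiff(landmark_list, keep)
  if (length(missing) > 0L)
    warning(sprintf("%d of %d landmark genes missing from the matrix",
                    length(missing), length(landmark_list)))
  mat[keep, , drop = FALSE]
}

#' log2(x + 1) transform of a TPM matrix
#'
#' @param mat numeric matrix of non-negative TPM values.
#' @return the transformed matrix.
#' @export
log2_tpm <- function(mat) {
  if (any(mat < 0, na.rm = TRUE))
    abort_validation("TPM values must be non-negative")
  log2(mat + 1)
}

#' Fit a per-feature standardization (z-score) scaler
#'
#' Centers each feature to mean zero and scales to unit standard deviation,
#' using the population SD (divisor n, not n - 1). Zero-variance features
#' are flagged and mapped to 0 by [apply_scaler()] with a warning rather
#' than producing NaN: small cohorts routinely contain constant features.
#'
#' @param x numeric matrix.
#' @param margin 1 if features are rows (expression: genes x specimens),
#'   2 if features are columns (descriptors: drugs x descriptors).
#' @param ddof degrees-of-freedom correction for the SD; 0 (population,
#'   default) or 1 (sample).
#' @return an object of class `pdx_scaler` holding per-feature center and
#'   scale, reusable on held-out data via [apply_scaler()].
#' @seealso [write_scaler()] for serialization.
#' @export
fit_scaler <- function(x, margin = 1, ddof = 0) {
  n_obs <- if (margin == 1) ncol(x) else nrow(x)
  if (n_obs < 2L)
    abort_validation("need at least 2 observations to fit a scaler")
  if (anyNA(x))
    abort_validation("scaler input must be complete (no missing values)")
  center <- apply(x, margin, mean)
  ss <- apply(x, margin, function(v) sum((v - mean(v))^2))
  scale <- sqrt(ss / (n_obs - ddof))
  ids <- dimnames(x)[[margin]]
  if (is.null(ids)) ids <- as.character(seq_along(center))
  structure(list(feature_ids = ids, center = unname(center),
                 scale = unname(scale), margin = as.integer(margin),
                 ddof = as.integer(ddof)),
            class = "pdx_scaler")
}

#' Apply a fitted scaler to new data
#'
#' @param scaler a [fit_scaler()] result (possibly reloaded with
#'   [read_scaler()]).
#' @param x numeric matrix with the same features, in the same order, along
#'   the scaler's margin.
#' @return the standardized matrix; zero-variance features become 0.
#' @export
apply_scaler <- function(scaler, x) {
  ids <- dimnames(x)[[scaler$margin]]
  if (!is.null(ids) && !identical(ids, scaler$feature_ids))
    abort_validation("feature IDs of `x` do not match the fitted scaler")
  zero <- scaler$scale == 0
  if (any(zero))
    warning(sprintf("%d zero-variance feature(s) set to 0", sum(zero)))
  safe_scale <- ifelse(zero, 1, scaler$scale)
  out <- if (scaler$margin == 1) {
    (x - scaler$center) / safe_scale
  } else {
    sweep(sweep(x, 2, scaler$center, "-"), 2, safe_scale, "/")
  }
  if (any(zero)) {
    if (scaler$margin == 1) out[zero, ] <- 0 else out[, zero] <- 0
  }
  out
}

#' Standardize expression profiles gene-wise
#'
#' Fits the per-gene scaler on `fit_specimens` only (by default all
#' specimens, reproducing a global standardization) and applies it to the
#' whole matrix. Fitting on the training fold of a split and applying to
#' held-out specimens avoids feature leakage across folds.
#'
#' @param mat log-transformed expression matrix, genes x specimens.
#' @param fit_specimens specimen IDs (columns) used to fit the scaler.
#' @return list with `values` (standardized matrix) and `scaler`.
#' @export
zscore_genes <- function(mat, fit_specimens = colnames(mat)) {
  scaler <- fit_scaler(mat[, fit_specimens, drop = FALSE], margin = 1)
  list(values = apply_scaler(scaler, mat), scaler = scaler)
}

#' Drop descriptor columns with any missing value
#'
#' Molecular descriptor tables routinely contain descriptors that cannot
#' be computed for every structure; any descriptor column missing for at
#' least one drug is removed so the remaining table is complete.
#'
#' @param tab numeric matrix or data.frame, drugs x descriptors.
#' @return the table restricted to complete columns, original order.
#' @export
filter_descriptors <- function(tab) {
  if (is.null(dim(tab)) || nrow(tab) == 0L || ncol(tab) == 0L)
    abort_validation("descriptor table must be non-empty")
  complete <- colSums(is.na(tab)) == 0L
  if (!any(complete))
    abort_validation("all descriptor columns contain missing values")
  tab[, complete, drop = FALSE]
}

#' Standardize drug descriptors across drugs
#'
#' @param tab complete descriptor table (after [filter_descriptors()]),
#'   drugs x descriptors.
#' @param fit_drugs drug IDs (rows) used to fit the scaler; default all.
#' @return list with `values` and `scaler`, as [zscore_genes()].
#' @export
zscore_descriptors <- function(tab, fit_drugs = rownames(tab)) {
  tab <- as.matrix(tab)
  scaler <- fit_scaler(tab[fit_drugs, , drop = FALSE], margin = 2)
  list(values = apply_scaler(scaler, tab), scaler = scaler)
}

#' Serialize / restore a fitted scaler as JSON
#'
#' @param scaler a `pdx_scaler`.
#' @param path file path for the JSON state.
#' @return `write_scaler()` returns `path` invisibly; `read_scaler()`
#'   returns the restored `pdx_scaler`.
#' @export
write_scaler <- function(scaler, path) {
  jsonlite::write_json(unclass(scaler), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(feature_ids = as.character(s$feature_ids),
                 center = as.numeric(s$center), scale = as.numeric(s$scale),
                 margin = as.integer(s$margin), ddof = as.integer(s$ddof)),
            class = "pdx_scaler")
}
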