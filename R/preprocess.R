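#' Remove small tumors and small non-malignant cell types
#'
#' Malignant cells are grouped by tumor of origin and non-malignant cells by
#' cell type; any group with fewer than `min_cells` cells is removed. The two
#' filters are applied jointly but independently: dropping a tumor's
#' malignant cells does not drop that tumor's non-malignant cells.
#'
#' @param matrix an [expression_matrix()].
#' @param annotation a [cell_annotation()] covering the matrix cells.
#' @param min_cells minimum group size to retain (default 50).
#' @return list with filtered `matrix` and `annotation`.
#' @export
filter_small_groups <- function(matrix, annotation, min_cells = 50) {
  stopifnot(min_cells >= 1)
  annotation <- cell_annotation(annotation, matrix = matrix)
  mal <- annotation$malignant
  keep <- logical(nrow(annotation))

  tum_tab <- table(annotation$tumor_id[mal])
  keep[mal] <- annotation$tumor_id[mal] %in% names(tum_tab)[tum_tab >= min_cells]

  ct_tab <- table(annotation$cell_type[!mal])
  keep[!mal] <- annotation$cell_type[!mal] %in% names(ct_tab)[ct_tab >= min_cells]

  if (!any(keep))
    stop("all cells removed by the group-size filter (min_cells = ",
         min_cells, ")")
  list(matrix = matrix[, keep, drop = FALSE],
       annotation = annotation[keep, , drop = FALSE])
}

#' Per-gene dropout rates
#'
#' The dropout rate of a gene is the fraction of cells in which its
#' expression value is exactly zero.
#'
#' @param matrix an [expression_matrix()].
#' @param annotation optional [cell_annotation()]; when `by_group` is given,
#'   rates are computed within each group.
#' @param by_group optional grouping column of the annotation
#'   (`"cell_type"` or `"tumor_id"`).
#' @return named numeric vector per gene, or a gene x group matrix when
#'   `by_group` is given.
#' @export
dropout_rates <- function(matrix, annotation = NULL, by_group = NULL) {
  if (ncol(matrix) == 0L) stop("empty matrix")
  x <- em_values(matrix)
  if (is.null(by_group)) return(rowMeans(x == 0))
  annotation <- cell_annotation(annotation, matrix = matrix)
  groups <- annotation[[by_group]]
  vapply(sort(unique(groups)), function(g) {
    rowMeans(x[, groups == g, drop = FALSE] == 0)
  }, numeric(nrow(x)))
}

#' Impute dropout zeros in high-dropout genes
#'
#' Imputation is restricted to genes whose dropout rate exceeds
#' `dropout_threshold`, to avoid over-imputation of well-detected genes.
#' The default `"neighbor_mean"` method replaces a zero entry by the mean of
#' that gene over the cell's `k` nearest neighbor cells, where neighbors are
#' found by correlation distance over the high-confidence genes (dropout at
#' or below the threshold), within the same cell type when an annotation is
#' supplied. A zero stays zero when all neighbors are zero. For any method
#' the contract is: genes at or below the threshold are untouched, nonzero
#' entries are never modified, and imputed values are non-negative.
#'
#' @param matrix an [expression_matrix()] in `log2tpm1` or `tpm` units.
#' @param dropout_threshold dropout rate above which a gene is eligible
#'   (default 0.5).
#' @param method `"neighbor_mean"` (default) or a function
#'   `f(matrix, eligible_genes, annotation)` returning a full matrix.
#' @param annotation optional [cell_annotation()] restricting neighbors to
#'   the same cell type.
#' @param k number of neighbor cells (default 10).
#' @return the imputed [expression_matrix()].
#' @export
impute_dropouts <- function(matrix, dropout_threshold = 0.5,
                            method = "neighbor_mean", annotation = NULL,
                            k = 10) {
  if (dropout_threshold < 0 || dropout_threshold > 1)
    stop("dropout_threshold must be in [0, 1]")
  if (!em_unit(matrix) %in% c("log2tpm1", "tpm"))
    stop("imputation expects log2tpm1 or tpm values")
  x <- em_values(matrix)
  rates <- rowMeans(x == 0)
  eligible <- rates > dropout_threshold
  if (!any(eligible)) return(matrix)

  if (is.function(method)) {
    out <- method(matrix, rownames(x)[eligible], annotation)
    out <- em_values(out)
  } else if (identical(method, "neighbor_mean")) {
    out <- impute_neighbor_mean(x, eligible, annotation, k)
  } else stop("unknown imputation method: ", method)

  # enforce the contract regardless of backend
  out[!eligible, ] <- x[!eligible, , drop = FALSE]
  nz <- x != 0
  out[nz] <- x[nz]
  out[out < 0] <- 0
  em_like(out, matrix)
}

impute_neighbor_mean <- function(x, eligible, annotation, k) {
  out <- x
  conf <- which(!eligible)
  if (length(conf) < 2L) {
    warning("fewer than 2 high-confidence genes; imputation skipped")
    return(out)
  }
  blocks <- if (is.null(annotation)) {
    list(seq_len(ncol(x)))
  } else {
    ann <- annotation[match(colnames(x), annotation$cell_id), ]
    split(seq_len(ncol(x)), ann$cell_type)
  }
  for (cells in blocks) {
    if (length(cells) < 2L) next
    sub <- x[conf, cells, drop = FALSE]
    cc <- suppressWarnings(stats::cor(sub))
    cc[!is.finite(cc)] <- -Inf
    diag(cc) <- -Inf
    kk <- min(k, length(cells) - 1L)
    for (ci in seq_along(cells)) {
      nb <- cells[order(cc[, ci], decreasing = TRUE)[seq_len(kk)]]
      zi <- which(eligible & x[, cells[ci]] == 0)
      if (length(zi))
        out[zi, cells[ci]] <- rowMeans(x[zi, nb, drop = FALSE])
    }
  }
  out
}

#' Pool single cells into pseudo-bulk profiles
#'
#' Reconstructs bulk-like expression profiles by averaging the TPM profiles
#' of all cells of a group (by default all cells of one tumor). Log-unit
#' input is un-logged to TPM, averaged, and re-logged, so the output unit
#' matches the input unit.
#'
#' @param matrix an [expression_matrix()] in `log2tpm1` or `tpm` units.
#' @param annotation a [cell_annotation()].
#' @param group_by annotation column defining the pools (default
#'   `"tumor_id"`).
#' @return an [expression_matrix()] with one column per group.
#' @export
pool_to_bulk <- function(matrix, annotation, group_by = "tumor_id") {
  unit <- em_unit(matrix)
  if (!unit %in% c("log2tpm1", "tpm"))
    stop("pooling expects log2tpm1 or tpm values")
  annotation <- cell_annotation(annotation, matrix = matrix)
  groups <- annotation[[group_by]]
  if (anyNA(groups) || any(!nzchar(groups))) stop("empty group label")
  tpm <- em_values(matrix)
  if (unit == "log2tpm1") tpm <- 2^tpm - 1
  lev <- sort(unique(groups))
  pooled <- vapply(lev, function(g) {
    idx <- which(groups == g)
    if (!length(idx)) stop("empty group: ", g)
    rowMeans(tpm[, idx, drop = FALSE])
  }, numeric(nrow(tpm)))
  pooled <- matrix(pooled, nrow = nrow(tpm),
                   dimnames = list(rownames(tpm), lev))
  if (unit == "log2tpm1") pooled <- log2(pooled + 1)
  expression_matrix(pooled, unit = unit)
}
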