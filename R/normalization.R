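#' Convert between TPM and length-scaled pseudo-counts
#'
#' Pseudo-counts are obtained by multiplying TPM values by gene length;
#' the inverse divides by length. The round trip is the identity up to
#' floating point error. Pseudo-counts are generally non-integer.
#'
#' @param matrix an [expression_matrix()] (`tpm` for `to_counts`, `counts`
#'   for `to_tpm`).
#' @param lengths a [gene_length_table()] covering all genes of the matrix.
#' @param direction `"to_counts"` or `"to_tpm"`.
#' @return converted [expression_matrix()].
#' @export
tpm_counts_convert <- function(matrix, lengths,
                               direction = c("to_counts", "to_tpm")) {
  direction <- match.arg(direction)
  lengths <- gene_length_table(lengths)
  missing <- setdiff(rownames(matrix), names(lengths))
  if (length(missing))
    stop("no gene length for: ", paste(missing, collapse = ", "))
  len <- as.numeric(lengths[rownames(matrix)])
  x <- em_values(matrix)
  if (direction == "to_counts") {
    if (em_unit(matrix) != "tpm") stop("to_counts expects unit 'tpm'")
    expression_matrix(x * len, unit = "counts")
  } else {
    if (em_unit(matrix) != "counts") stop("to_tpm expects unit 'counts'")
    expression_matrix(x / len, unit = "tpm")
  }
}

#' Per-cell size factors
#'
#' Computes size factors on a count matrix by one of four methods:
#' relative log expression (`"rle"`, median-of-ratios), trimmed mean of
#' M-values (`"tmm"`), upper quartile (`"upper_quartile"`), or pooling
#' deconvolution (`"deconvolution"`, computed within annotated cell types).
#' Only reference genes — genes with dropout rate below
#' `reference_dropout_max` — enter the computation, which shields the
#' factors from noise in rarely detected genes.
#'
#' TMM and upper-quartile factors are effective-library-size factors
#' (library size times the method's normalization factor). Deconvolution
#' pools cells within each cell type (ring ordering by library size, a
#' ladder of pool sizes capped at the group size), normalizes pool sums and
#' solves back to per-cell factors. RLE factors are rescaled to geometric
#' mean 1; all other methods to arithmetic mean 1.
#'
#' @param counts an [expression_matrix()] with unit `"counts"` (integer or
#'   pseudo-counts).
#' @param method one of `"rle"`, `"tmm"`, `"upper_quartile"`,
#'   `"deconvolution"`.
#' @param annotation [cell_annotation()]; required for `"deconvolution"`.
#' @param reference_dropout_max reference-gene dropout cutoff (default
#'   0.75).
#' @param pool_sizes pool-size ladder for deconvolution (default
#'   20, 40, 60, 80, 100, capped at the smallest group).
#' @return named numeric vector of positive factors (class `size_factors`,
#'   with a `method` attribute), one per cell.
#' @export
size_factors <- function(counts,
                         method = c("rle", "tmm", "upper_quartile",
                                    "deconvolution"),
                         annotation = NULL,
                         reference_dropout_max = 0.75,
                         pool_sizes = c(20, 40, 60, 80, 100)) {
  method <- match.arg(method)
  if (em_unit(counts) != "counts") stop("size factors expect unit 'counts'")
  if (ncol(counts) < 2L) stop("need at least 2 cells")
  x <- em_values(counts)
  ref <- rowMeans(x == 0) < reference_dropout_max
  if (!any(ref)) stop("no reference genes below the dropout cutoff")
  xr <- x[ref, , drop = FALSE]
  empty <- colSums(xr) == 0
  if (any(empty))
    stop("cells with zero counts on all reference genes: ",
         paste(colnames(x)[empty], collapse = ", "))

  sf <- switch(method,
    rle = {
      s <- DESeq2::estimateSizeFactorsForMatrix(xr)
      s / exp(mean(log(s)))
    },
    tmm = ,
    upper_quartile = {
      em <- if (method == "tmm") "TMM" else "upperquartile"
      f <- edgeR::calcNormFactors(xr, method = em)
      s <- colSums(xr) * f
      s / mean(s)
    },
    deconvolution = {
      if (is.null(annotation))
        stop("deconvolution needs a cell annotation with cell types")
      ann <- cell_annotation(annotation, matrix = counts)
      min_n <- min(table(ann$cell_type))
      sizes <- unique(pmin(pool_sizes, min_n))
      s <- tryCatch(
        scran::calculateSumFactors(xr, clusters = ann$cell_type,
                                   sizes = sizes, positive = TRUE),
        error = function(e)
          stop("deconvolution failed (", conditionMessage(e),
               "); consider larger pools or fewer cell types"))
      s / mean(s)
    })
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("non-positive size factor produced by method ", method)
  structure(stats::setNames(as.numeric(sf), colnames(x)),
            method = method, class = c("size_factors", "numeric"))
}

#' Normalize counts by size factors and return log2(TPM + 1)
#'
#' Each cell's counts are divided by its size factor, transformed back to
#' the TPM scale by dividing gene lengths, and log2(x + 1) transformed.
#'
#' @param counts [expression_matrix()] with unit `"counts"`.
#' @param factors a [size_factors()] vector covering all cells.
#' @param lengths [gene_length_table()] covering all genes.
#' @return [expression_matrix()] with unit `"log2tpm1"`.
#' @export
apply_size_factors <- function(counts, factors, lengths) {
  if (em_unit(counts) != "counts") stop("expects unit 'counts'")
  missing <- setdiff(colnames(counts), names(factors))
  if (length(missing))
    stop("no size factor for cells: ", paste(missing, collapse = ", "))
  norm <- sweep(em_values(counts), 2, as.numeric(factors[colnames(counts)]), "/")
  tpm <- tpm_counts_convert(expression_matrix(norm, unit = "counts"),
                            lengths, "to_tpm")
  expression_matrix(log2(em_values(tpm) + 1), unit = "log2tpm1")
}

#' Rank normalization methods by cross-cell-type distribution agreement
#'
#' For each method the counts are normalized, cell-type mean expression and
#' per-gene relative expression are computed, and the method is scored by
#' the mean two-sample Kolmogorov-Smirnov statistic between the
#' distributions of log relative expression of every pair of cell types.
#' A method that removes technical cell-type-level biases makes these
#' distributions agree, so methods are ranked ascending by score and the
#' first is the selected method.
#'
#' @param counts [expression_matrix()] with unit `"counts"`.
#' @param annotation [cell_annotation()] with at least 2 cell types.
#' @param lengths [gene_length_table()].
#' @param gene_sets optional [gene_set_collection()]; when given, scoring is
#'   restricted to genes belonging to at least one set.
#' @param methods methods to evaluate (default all four).
#' @param reference_dropout_max passed to [size_factors()].
#' @return data.frame (method, score) sorted ascending by score, with the
#'   winning method in attribute `"selected"`.
#' @export
evaluate_normalizations <- function(counts, annotation, lengths,
                                    gene_sets = NULL,
                                    methods = c("rle", "tmm",
                                                "upper_quartile",
                                                "deconvolution"),
                                    reference_dropout_max = 0.75) {
  annotation <- cell_annotation(annotation, matrix = counts)
  types <- unique(annotation$cell_type)
  if (length(types) < 2L) stop("need at least 2 cell types")
  scores <- vapply(methods, function(m) {
    sf <- size_factors(counts, m, annotation = annotation,
                       reference_dropout_max = reference_dropout_max)
    norm <- apply_size_factors(counts, sf, lengths)
    if (!is.null(gene_sets)) {
      keep <- intersect(rownames(norm), unique(unlist(gene_sets)))
      norm <- norm[keep, , drop = FALSE]
    }
    E <- celltype_means(norm, annotation)
    r <- relative_expression(E)
    rv <- r$r[r$valid, , drop = FALSE]
    pairs <- utils::combn(colnames(rv), 2, simplify = FALSE)
    ks <- vapply(pairs, function(p) {
      a <- log(rv[, p[1]]); b <- log(rv[, p[2]])
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (!length(a) || !length(b)) return(0)
      unname(suppressWarnings(stats::ks.test(a, b)$statistic))
    }, numeric(1))
    mean(ks)
  }, numeric(1))
  out <- data.frame(method = methods, score = unname(scores),
                    stringsAsFactors = FALSE)
  out <- out[order(out$score, out$method), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "selected") <- out$method[1]
  out
}
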