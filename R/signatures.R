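#' Per-cell gene-set signature score
#'
#' The unweighted mean log2(TPM + 1) expression of a gene set's members in
#' each cell — the standard "average expression of a signature" score used
#' e.g. for hypoxia response, glycolysis or OXPHOS activity of single
#' cells.
#'
#' @param matrix an [expression_matrix()] (log2(TPM + 1)).
#' @param gene_set character vector of gene ids; must intersect the
#'   matrix.
#' @param set_name optional label stored on the result.
#' @return named numeric vector of per-cell scores with attributes
#'   `set_name` and `n_genes_used`.
#' @export
cell_set_score <- function(matrix, gene_set, set_name = NULL) {
  genes <- intersect(gene_set, rownames(matrix))
  if (!length(genes)) stop("gene set does not intersect the matrix")
  s <- colMeans(em_values(matrix)[genes, , drop = FALSE])
  structure(s, set_name = set_name, n_genes_used = length(genes))
}

#' Correlation between two per-cell scores
#'
#' @param score_a,score_b named numeric vectors (cell id -> score); cells
#'   missing from either side are dropped and counted.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `estimate`, `p_value`, `n`, `n_dropped` and
#'   `defined` (FALSE when either score has zero variance, in which case
#'   the estimate is NA rather than an error).
#' @export
score_correlation <- function(score_a, score_b,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  cells <- intersect(names(score_a), names(score_b))
  n_dropped <- (length(score_a) - length(cells)) +
    (length(score_b) - length(cells))
  if (length(cells) < 3L) stop("need at least 3 shared cells")
  a <- as.numeric(score_a[cells]); b <- as.numeric(score_b[cells])
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(estimate = NA_real_, p_value = NA_real_,
                n = length(cells), n_dropped = n_dropped,
                defined = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(a, b, method = method))
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n = length(cells), n_dropped = n_dropped, defined = TRUE)
}

#' Pairwise gene-gene correlations between two gene sets
#'
#' Pearson correlation of every (gene of set A, gene of set B) pair over a
#' subset of cells, with the fraction of positive correlations as a
#' summary. Constant genes are excluded with a warning; self-pairs (when
#' the sets share genes) are excluded from the summary.
#'
#' @param matrix an [expression_matrix()].
#' @param set_a,set_b character vectors of gene ids.
#' @param cells_subset optional character vector of cell ids.
#' @return list with `correlations` (|A| x |B| matrix) and
#'   `fraction_positive`.
#' @export
pairwise_gene_correlations <- function(matrix, set_a, set_b,
                                       cells_subset = NULL) {
  x <- em_values(matrix)
  if (!is.null(cells_subset)) x <- x[, cells_subset, drop = FALSE]
  ga <- intersect(set_a, rownames(x))
  gb <- intersect(set_b, rownames(x))
  if (!length(ga) || !length(gb))
    stop("gene sets do not intersect the matrix")
  const <- rownames(x)[apply(x, 1L, stats::sd) == 0]
  drop_a <- intersect(ga, const); drop_b <- intersect(gb, const)
  if (length(drop_a) || length(drop_b)) {
    warning("constant genes excluded: ",
            paste(union(drop_a, drop_b), collapse = ", "))
    ga <- setdiff(ga, const); gb <- setdiff(gb, const)
  }
  if (!length(ga) || !length(gb)) stop("no variable genes left")
  cc <- stats::cor(t(x[ga, , drop = FALSE]), t(x[gb, , drop = FALSE]))
  off_diag <- !(outer(ga, gb, "=="))
  list(correlations = cc,
       fraction_positive = mean(cc[off_diag] > 0))
}

#' Relative mutual information between two labelings
#'
#' Mutual information of two partitions of the same cells, normalized by
#' the smaller of the two label entropies (natural logs), so that a
#' labeling that is a refinement of the other — or identical up to label
#' renaming — scores exactly 1, and independent labelings score near 0.
#' When both labelings have a single cluster the agreement is degenerate
#' and defined as 1 (with attribute `degenerate = TRUE`).
#'
#' @param labels_a,labels_b vectors of cluster labels over the same cells
#'   (aligned by position, or by names when both are named).
#' @param normalization `"min"` (default), `"max"`, `"mean"` or
#'   `"sqrt"` entropy normalizations.
#' @return a number in \[0, 1\].
#' @export
relative_mutual_information <- function(labels_a, labels_b,
                                        normalization = c("min", "max",
                                                          "mean", "sqrt")) {
  normalization <- match.arg(normalization)
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    cells <- intersect(names(labels_a), names(labels_b))
    if (length(cells) != length(labels_a) ||
        length(cells) != length(labels_b))
      stop("labelings cover different cells")
    labels_b <- labels_b[names(labels_a)]
  }
  if (length(labels_a) != length(labels_b))
    stop("labelings have different lengths")
  tab <- table(labels_a, labels_b)
  pj <- tab / sum(tab)
  pa <- rowSums(pj); pb <- colSums(pj)
  ha <- entropy_nat(pa); hb <- entropy_nat(pb)
  if (ha == 0 && hb == 0)
    return(structure(1, degenerate = TRUE))
  mi <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb)) {
    if (pj[i, j] > 0)
      mi <- mi + pj[i, j] * log(pj[i, j] / (pa[i] * pb[j]))
  }
  denom <- switch(normalization,
                  min = min(ha, hb), max = max(ha, hb),
                  mean = (ha + hb) / 2, sqrt = sqrt(ha * hb))
  if (denom == 0) return(structure(1, degenerate = TRUE))
  max(0, min(1, mi / denom))
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}
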