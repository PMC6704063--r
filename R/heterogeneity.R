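#' PCA-loading variability scores for genes
#'
#' Ranks genes by how much they contribute to expression variance within a
#' group of cells. A PCA (genes as variables, cells as observations,
#' centered but not scaled) is run on the un-imputed log2(TPM + 1) values;
#' a gene's score is the sum of the absolute values of its loadings over
#' the smallest leading set of principal components whose cumulative
#' variance fraction reaches `variance_threshold`.
#'
#' @param matrix an [expression_matrix()] (`log2tpm1`, not imputed).
#' @param cells_subset optional character vector of cell ids (e.g. the
#'   malignant cells of one tumor); default all cells.
#' @param variance_threshold cumulative variance fraction selecting the top
#'   PCs (default 0.80).
#' @param center,scale. passed to [stats::prcomp()] (defaults TRUE/FALSE,
#'   standard centered unscaled PCA).
#' @return data.frame (gene, score) sorted descending by score with gene id
#'   as tie-break; attributes `metric = "pca"`, `n_top_pcs`,
#'   `variance_threshold`.
#' @export
pca_gene_scores <- function(matrix, cells_subset = NULL,
                            variance_threshold = 0.80,
                            center = TRUE, scale. = FALSE) {
  x <- em_values(matrix)
  if (!is.null(cells_subset)) {
    missing <- setdiff(cells_subset, colnames(x))
    if (length(missing))
      stop("cells not in matrix: ", paste(missing, collapse = ", "))
    x <- x[, cells_subset, drop = FALSE]
  }
  if (ncol(x) < 2L) stop("need at least 2 cells")
  if (all(apply(x, 1L, stats::var) == 0))
    stop("constant matrix: no variance to decompose")
  pc <- stats::prcomp(t(x), center = center, scale. = scale.)
  v <- pc$sdev^2
  v <- v[v > .Machine$double.eps * max(v)]
  frac <- cumsum(v) / sum(v)
  k <- which(frac >= variance_threshold)[1]
  if (is.na(k)) k <- length(v)
  score <- rowSums(abs(pc$rotation[, seq_len(k), drop = FALSE]))
  rank_genes(score, metric = "pca", n_top_pcs = k,
             variance_threshold = variance_threshold)
}

#' Dispersion-based variability scores (CV or SD)
#'
#' Simpler alternatives to the PCA score: the per-gene sample standard
#' deviation across cells, or the coefficient of variation (SD divided by
#' mean). CV is undefined for genes with zero mean; such genes are
#' excluded.
#'
#' @inheritParams pca_gene_scores
#' @param metric `"cv"` or `"sd"`.
#' @return data.frame (gene, score) sorted as in [pca_gene_scores()].
#' @export
dispersion_scores <- function(matrix, cells_subset = NULL,
                              metric = c("cv", "sd")) {
  metric <- match.arg(metric)
  x <- em_values(matrix)
  if (!is.null(cells_subset)) x <- x[, cells_subset, drop = FALSE]
  if (ncol(x) < 2L) stop("need at least 2 cells")
  sds <- apply(x, 1L, stats::sd)
  score <- if (metric == "sd") sds else {
    mu <- rowMeans(x)
    s <- sds / mu
    s[mu <= 0] <- NA_real_
    s
  }
  keep <- !is.na(score)
  rank_genes(score[keep], metric = metric)
}

rank_genes <- function(score, metric, ...) {
  ord <- order(-score, names(score))
  out <- data.frame(gene = names(score)[ord], score = unname(score[ord]),
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  attr(out, "metric") <- metric
  out
}

#' GSEA on a gene variability ranking
#'
#' Runs pre-ranked gene set enrichment on a descending variability ranking
#' (from [pca_gene_scores()] or [dispersion_scores()]), identifying
#' pathways enriched in the most variable genes.
#'
#' @param ranking data.frame (gene, score) from the ranking functions, or a
#'   named numeric vector.
#' @param gene_sets a [gene_set_collection()].
#' @param n_perm,seed,... passed to [preranked_gsea()].
#' @return data.frame of GSEA results sorted by p then normalized score.
#' @export
heterogeneity_enrichment <- function(ranking, gene_sets, n_perm = 1000,
                                     seed = 1, ...) {
  stats <- if (is.data.frame(ranking)) {
    stats::setNames(ranking$score, ranking$gene)
  } else ranking
  if (!length(stats)) stop("empty ranking")
  preranked_gsea(stats, gene_sets, n_perm = n_perm, seed = seed, ...)
}
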