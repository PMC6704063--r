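#' Cell-type mean expression
#'
#' Arithmetic mean expression of each gene within each annotated cell type
#' (the E matrix of the pathway activity model).
#'
#' @param matrix an [expression_matrix()], normally `log2tpm1` after
#'   normalization.
#' @param annotation a [cell_annotation()], or a character/factor vector of
#'   group labels aligned to the matrix columns.
#' @return gene x cell-type matrix of means.
#' @export
celltype_means <- function(matrix, annotation) {
  labels <- if (is.data.frame(annotation)) {
    cell_annotation(annotation, matrix = matrix)$cell_type
  } else {
    if (length(annotation) != ncol(matrix))
      stop("label vector length does not match number of cells")
    as.character(annotation)
  }
  f <- factor(labels)
  empty <- levels(f)[tabulate(f, nbins = nlevels(f)) == 0L]
  if (length(empty)) {
    warning("cell types with no cells excluded: ",
            paste(empty, collapse = ", "))
    f <- droplevels(f)
  }
  group_means(em_values(matrix), f)
}

# fast grouped row means: x %*% (indicator / n_j)
group_means <- function(x, f) {
  G <- stats::model.matrix(~ f - 1)
  G <- sweep(G, 2, colSums(G), "/")
  E <- x %*% G
  colnames(E) <- levels(f)
  E
}

#' Relative expression across cell types
#'
#' Each gene's cell-type mean divided by its average over all cell types,
#' so a value above 1 marks higher-than-average expression of the gene in
#' that cell type. Genes whose across-type mean is zero have no defined
#' ratio and are flagged invalid. For every valid gene the ratios average
#' to 1 across cell types by construction.
#'
#' @param means gene x cell-type matrix from [celltype_means()].
#' @return list with `r` (gene x cell-type ratio matrix, NA rows for
#'   invalid genes) and `valid` (logical per gene).
#' @export
relative_expression <- function(means) {
  if (ncol(means) < 2L) stop("need at least 2 cell types")
  avg <- rowMeans(means)
  valid <- avg > 0
  r <- means / avg
  r[!valid, ] <- NA_real_
  list(r = r, valid = valid)
}

#' Gene weights from gene-set membership
#'
#' Weight of a gene = 1 / number of gene sets that contain it, so genes
#' shared between pathways contribute proportionally less to each.
#'
#' @param gene_sets a [gene_set_collection()].
#' @return named numeric vector of weights in (0, 1].
#' @export
gene_weights <- function(gene_sets) {
  counts <- table(unlist(lapply(gene_sets, unique)))
  stats::setNames(1 / as.numeric(counts), names(counts))
}

#' Pathway activity scores
#'
#' The activity of a pathway in a cell type is the weighted average of the
#' relative expression of its member genes, with weights from
#' [gene_weights()]. Before averaging, outlier genes are excluded per
#' pathway: a member gene is an outlier when any of its relative-expression
#' values exceeds `outlier_hi` times the 75th percentile, or falls below
#' `outlier_lo` times the 25th percentile, of the pathway's pooled
#' relative-expression values across all cell types. An outlier is removed
#' from that pathway in every cell type, keeping scores comparable across
#' types. A pathway with no surviving gene gets an NA score (flagged), not
#' zero.
#'
#' @param relexpr result of [relative_expression()].
#' @param gene_sets a [gene_set_collection()].
#' @param weights [gene_weights()] computed from the same collection
#'   (computed automatically when NULL).
#' @param outlier_hi,outlier_lo outlier multipliers (defaults 3 and 1/3).
#' @return `pathway_activity` data.frame with columns pathway, group,
#'   score, n_genes_used, n_outliers; excluded genes per pathway in
#'   attribute `"outliers"`.
#' @export
pathway_scores <- function(relexpr, gene_sets, weights = NULL,
                           outlier_hi = 3, outlier_lo = 1 / 3) {
  if (is.null(weights)) weights <- gene_weights(gene_sets)
  prep <- prepare_pathways(relexpr$r, relexpr$valid, gene_sets, weights)
  sc <- score_pathways(relexpr$r, prep, outlier_hi, outlier_lo,
                       record_outliers = TRUE)
  groups <- colnames(relexpr$r)
  out <- data.frame(
    pathway = rep(rownames(sc$scores), times = ncol(sc$scores)),
    group = rep(groups, each = nrow(sc$scores)),
    score = as.vector(sc$scores),
    n_genes_used = rep(sc$n_used, times = ncol(sc$scores)),
    n_outliers = rep(lengths(sc$outliers), times = ncol(sc$scores)),
    stringsAsFactors = FALSE)
  structure(out, outliers = sc$outliers,
            class = c("pathway_activity", "data.frame"))
}

# resolve sets to row indices of r, keeping only valid genes with weights
prepare_pathways <- function(r, valid, gene_sets, weights) {
  genes <- rownames(r)
  lapply(gene_sets, function(set) {
    g <- intersect(set, genes[valid])
    idx <- match(g, genes)
    list(idx = idx, w = as.numeric(weights[g]), genes = g)
  })
}

# core of the activity score; shared by observed and permuted passes
score_pathways <- function(r, prep, outlier_hi, outlier_lo,
                           record_outliers = FALSE) {
  nty <- ncol(r)
  scores <- matrix(NA_real_, length(prep), nty,
                   dimnames = list(names(prep), colnames(r)))
  n_used <- integer(length(prep))
  outliers <- if (record_outliers) vector("list", length(prep))
  for (t in seq_along(prep)) {
    p <- prep[[t]]
    if (!length(p$idx)) next
    rv <- r[p$idx, , drop = FALSE]
    pool <- as.vector(rv)
    qs <- stats::quantile(pool, c(0.25, 0.75), names = FALSE)
    bad <- apply(rv, 1L, function(v)
      any(v > outlier_hi * qs[2] | v < outlier_lo * qs[1]))
    keep <- which(!bad)
    n_used[t] <- length(keep)
    if (record_outliers) outliers[[t]] <- p$genes[bad]
    if (!length(keep)) next
    w <- p$w[keep]
    scores[t, ] <- colSums(rv[keep, , drop = FALSE] * w) / sum(w)
  }
  if (record_outliers) names(outliers) <- names(prep)
  list(scores = scores, n_used = n_used, outliers = outliers)
}

#' Permutation test for cell-type pathway activity
#'
#' Group labels are randomly reshuffled across cells `n_perm` times, and
#' the whole score chain (cell-type means, relative expression, weighted
#' pathway scores with outlier exclusion) is recomputed per shuffle to
#' build a null distribution for every pathway/cell-type pair. The
#' directional tail is the fraction of null scores above the observed score
#' when it exceeds 1, or below it when it is under 1; an observed score of
#' exactly 1 gets p = 1. With the default `p_type = "two_sided"` the
#' directional tail is doubled (capped at 1), which is calibrated under the
#' null; `p_type = "directional"` reports the one-sided tail itself. The
#' add-one smoothing `(1 + b) / (1 + n)` keeps p away from zero; setting
#' `smooth = FALSE` gives the raw fraction `b / n`.
#'
#' @param matrix an [expression_matrix()] (normalized `log2tpm1`).
#' @param annotation a [cell_annotation()] or label vector (>= 2 groups).
#' @param gene_sets a [gene_set_collection()].
#' @param n_perm number of label shuffles (default 5000; 1000 is typical
#'   for bulk data).
#' @param seed RNG seed, recorded in the result.
#' @param p_type `"two_sided"` (default, calibrated) or `"directional"`.
#' @param smooth use add-one smoothing (default TRUE).
#' @param outlier_hi,outlier_lo passed to the scoring step.
#' @return `pathway_activity` data.frame with columns pathway, group,
#'   score, p_value, n_genes_used, n_outliers; attributes `n_perm`,
#'   `seed`, `p_type`, `outliers`.
#' @export
permutation_test <- function(matrix, annotation, gene_sets,
                             n_perm = 5000, seed = 1,
                             p_type = c("two_sided", "directional"),
                             smooth = TRUE,
                             outlier_hi = 3, outlier_lo = 1 / 3) {
  p_type <- match.arg(p_type)
  if (n_perm < 100) stop("n_perm must be at least 100")
  labels <- if (is.data.frame(annotation)) {
    cell_annotation(annotation, matrix = matrix)$cell_type
  } else as.character(annotation)
  if (length(unique(labels)) < 2L) stop("need at least 2 groups")

  # restrict to genes that can contribute: union of set members
  keep <- intersect(rownames(matrix), unique(unlist(gene_sets)))
  x <- em_values(matrix)[keep, , drop = FALSE]
  f <- factor(labels)
  weights <- gene_weights(gene_sets)

  chain <- function(fl) {
    E <- group_means(x, fl)
    re <- relative_expression(E)
    prep <- prepare_pathways(re$r, re$valid, gene_sets, weights)
    score_pathways(re$r, prep, outlier_hi, outlier_lo,
                   record_outliers = TRUE)
  }
  obs <- chain(f)

  res <- permutation_core(x, f, gene_sets, weights, n_perm, seed,
                          outlier_hi, outlier_lo, obs)
  pt <- perm_pvalues(obs$scores, res$hi, res$lo, res$nv, p_type, smooth)

  groups <- colnames(obs$scores)
  out <- data.frame(
    pathway = rep(rownames(obs$scores), times = ncol(obs$scores)),
    group = rep(groups, each = nrow(obs$scores)),
    score = as.vector(obs$scores),
    p_value = as.vector(pt),
    n_genes_used = rep(obs$n_used, times = ncol(obs$scores)),
    n_outliers = rep(lengths(obs$outliers), times = ncol(obs$scores)),
    stringsAsFactors = FALSE)
  structure(out, outliers = obs$outliers, n_perm = n_perm, seed = seed,
            p_type = p_type, class = c("pathway_activity", "data.frame"))
}

permutation_core <- function(x, f, gene_sets, weights, n_perm, seed,
                             outlier_hi, outlier_lo, obs) {
  set.seed(seed)
  n_cells <- length(f)
  hi <- lo <- nv <- matrix(0, nrow(obs$scores), ncol(obs$scores))
  for (b in seq_len(n_perm)) {
    fp <- f[sample.int(n_cells)]
    E <- group_means(x, fp)
    re <- relative_expression(E)
    prep <- prepare_pathways(re$r, re$valid, gene_sets, weights)
    ns <- score_pathways(re$r, prep, outlier_hi, outlier_lo)$scores
    ok <- !is.na(ns) & !is.na(obs$scores)
    hi[ok] <- hi[ok] + (ns[ok] > obs$scores[ok])
    lo[ok] <- lo[ok] + (ns[ok] < obs$scores[ok])
    nv[ok] <- nv[ok] + 1
  }
  list(hi = hi, lo = lo, nv = nv)
}

perm_pvalues <- function(scores, hi, lo, nv, p_type, smooth) {
  b <- ifelse(scores > 1, hi, lo)
  p <- if (smooth) (1 + b) / (1 + nv) else b / pmax(nv, 1)
  if (p_type == "two_sided") p <- pmin(1, 2 * p)
  p[!is.na(scores) & scores == 1] <- 1
  p[is.na(scores)] <- NA_real_
  p
}

#' Pathway activity for bulk sample groups
#'
#' The same relative-expression pathway activity machinery applied to bulk
#' expression profiles, with sample groups (e.g. tumor vs matched normal)
#' playing the role of cell types. The permutation default drops to 1000,
#' the typical choice for bulk cohorts.
#'
#' @param bulk_matrix an [expression_matrix()] of samples in columns.
#' @param sample_labels character/factor of group labels per sample.
#' @param gene_sets a [gene_set_collection()].
#' @param n_perm default 1000.
#' @param seed RNG seed.
#' @param ... passed to [permutation_test()].
#' @return a `pathway_activity` data.frame as for [permutation_test()].
#' @export
bulk_group_activity <- function(bulk_matrix, sample_labels, gene_sets,
                                n_perm = 1000, seed = 1, ...) {
  permutation_test(bulk_matrix, sample_labels, gene_sets,
                   n_perm = n_perm, seed = seed, ...)
}
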