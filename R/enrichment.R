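#' Weighted running-sum enrichment score
#'
#' The classic weighted Kolmogorov-Smirnov-like statistic over a ranked
#' gene list. Walking down the ranking, the running sum increases by
#' `|score|^weight_exponent` (normalized by the sum over set members) at
#' each gene that belongs to the set, and decreases by `1/(N - n_set)` at
#' each gene that does not. The enrichment score (ES) is the running-sum
#' value of largest magnitude; the leading edge is the set members at or
#' before the extremum for a positive ES, or at or after it for a negative
#' ES. With `weight_exponent = 0` every hit counts equally and the
#' statistic reduces to the unweighted KS walk. Genes with zero score
#' contribute zero hit weight for positive exponents.
#'
#' @param ranked_genes character vector of unique gene ids, ranked.
#' @param ranked_scores numeric scores sorted in decreasing order,
#'   aligned with `ranked_genes`.
#' @param gene_set character vector; must intersect the ranking.
#' @param weight_exponent exponent on `|score|` for hit increments
#'   (default 1).
#' @return list with `es`, `running_sum` (length N), `leading_edge`
#'   (character) and `hits` (indices of set members in the ranking).
#' @export
enrichment_score <- function(ranked_genes, ranked_scores, gene_set,
                             weight_exponent = 1) {
  n <- length(ranked_genes)
  if (length(ranked_scores) != n) stop("genes and scores lengths differ")
  if (anyDuplicated(ranked_genes)) stop("ranked genes must be unique")
  if (is.unsorted(rev(ranked_scores)))
    stop("ranked_scores must be sorted in decreasing order")
  hit <- ranked_genes %in% gene_set
  nh <- sum(hit)
  if (nh == 0L) stop("gene set does not intersect the ranked list")
  if (nh == n) stop("gene set covers the whole ranked list")

  w <- numeric(n)
  w[hit] <- abs(ranked_scores[hit])^weight_exponent
  sw <- sum(w)
  step <- if (sw > 0) w / sw else {
    # all hit weights vanish (all-zero scores): no hit increments
    numeric(n)
  }
  step[!hit] <- -1 / (n - nh)
  rs <- cumsum(step)
  i_max <- which.max(rs)
  i_min <- which.min(rs)
  es <- if (rs[i_max] >= -rs[i_min]) rs[i_max] else rs[i_min]
  leading <- if (es >= 0) {
    ranked_genes[hit & seq_len(n) <= i_max]
  } else {
    ranked_genes[hit & seq_len(n) >= i_min]
  }
  list(es = es, running_sum = rs, leading_edge = leading,
       hits = which(hit))
}

#' Pre-ranked GSEA with a gene-set permutation null
#'
#' For each gene set (after intersecting with the ranked universe and
#' filtering to sizes within `[set_min, set_max]`) the enrichment score is
#' computed, and its null distribution is built from `n_perm` random gene
#' sets of the same size drawn from the ranked universe. The normalized
#' enrichment score (NES) divides the ES by the mean magnitude of
#' same-signed null scores, and the p-value is the add-one-smoothed
#' fraction of same-signed null scores at least as extreme.
#'
#' @param ranking named numeric vector of gene scores (sorted internally,
#'   decreasing, ties broken by gene id for reproducibility).
#' @param gene_sets a [gene_set_collection()] or named list.
#' @param n_perm permutations per set (default 1000).
#' @param set_min,set_max size bounds after intersection (defaults 5, 500).
#' @param seed RNG seed.
#' @param weight_exponent passed to [enrichment_score()].
#' @return data.frame with columns set, es, nes, p_value, size,
#'   leading_edge (comma-joined), sorted by p then decreasing |NES|;
#'   attributes `n_perm`, `seed`. Empty (with a warning) when no set is
#'   within the size bounds.
#' @export
preranked_gsea <- function(ranking, gene_sets, n_perm = 1000,
                           set_min = 5, set_max = 500, seed = 1,
                           weight_exponent = 1) {
  if (is.null(names(ranking))) stop("ranking must be a named vector")
  ord <- order(-ranking, names(ranking))
  genes <- names(ranking)[ord]
  scores <- as.numeric(ranking[ord])

  sizes <- vapply(gene_sets, function(s) length(intersect(s, genes)),
                  integer(1))
  keep <- sizes >= set_min & sizes <= set_max & sizes < length(genes)
  if (!any(keep)) {
    warning("no gene set within size bounds after intersection")
    return(empty_gsea_result(n_perm, seed))
  }
  gene_sets <- gene_sets[keep]
  sizes <- sizes[keep]

  set.seed(seed)
  rows <- lapply(seq_along(gene_sets), function(t) {
    obs <- enrichment_score(genes, scores, gene_sets[[t]], weight_exponent)
    null_es <- vapply(seq_len(n_perm), function(b) {
      rnd <- sample(genes, sizes[t])
      enrichment_score(genes, scores, rnd, weight_exponent)$es
    }, numeric(1))
    same <- null_es[sign(null_es) == sign(obs$es)]
    nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    data.frame(set = names(gene_sets)[t], es = obs$es, nes = nes,
               p_value = p, size = sizes[t],
               leading_edge = paste(obs$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, -abs(out$nes), out$set), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}

empty_gsea_result <- function(n_perm, seed) {
  out <- data.frame(set = character(), es = numeric(), nes = numeric(),
                    p_value = numeric(), size = integer(),
                    leading_edge = character(), stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}

#' Two-class GSEA with the difference-of-class-means metric
#'
#' Genes are ranked by the difference between their mean expression in the
#' first class and in the second class (on log2 values), descending; the
#' ranking then goes through [preranked_gsea()] with its gene-set
#' permutation null. Swapping the class labels negates every enrichment
#' score.
#'
#' @param matrix an [expression_matrix()].
#' @param class_labels character/factor with exactly two levels aligned to
#'   the matrix columns; the first level (alphabetical, or factor level
#'   order) is class 1.
#' @param gene_sets a [gene_set_collection()].
#' @param n_perm,set_min,set_max,seed,weight_exponent as
#'   [preranked_gsea()].
#' @return data.frame as [preranked_gsea()], with attribute `classes`.
#' @export
two_class_gsea <- function(matrix, class_labels, gene_sets, n_perm = 1000,
                           set_min = 5, set_max = 500, seed = 1,
                           weight_exponent = 1) {
  f <- factor(class_labels)
  if (nlevels(f) != 2L) stop("exactly two classes required")
  if (any(table(f) < 3L)) stop("each class needs at least 3 cells")
  if (length(f) != ncol(matrix))
    stop("class labels do not match number of cells")
  x <- em_values(matrix)
  metric <- rowMeans(x[, f == levels(f)[1], drop = FALSE]) -
    rowMeans(x[, f == levels(f)[2], drop = FALSE])
  out <- preranked_gsea(metric, gene_sets, n_perm = n_perm,
                        set_min = set_min, set_max = set_max, seed = seed,
                        weight_exponent = weight_exponent)
  attr(out, "classes") <- levels(f)
  out
}
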