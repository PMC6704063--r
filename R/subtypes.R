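#' Classify T cells into CD4+ and CD8+ subtypes
#'
#' Threshold rules on the log2(TPM + 1) expression of the two markers:
#' CD4 above `threshold` with CD8A below it gives CD4; CD8A above with CD4
#' below gives CD8; both above gives `excluded` (likely doublets or
#' ambiguous cells); anything else — including values exactly at the
#' threshold — is `unassigned`.
#'
#' @param matrix an [expression_matrix()] of T cells (log2(TPM + 1)).
#' @param threshold marker expression cutoff (default 1).
#' @param cd4_gene,cd8_gene marker gene ids (defaults `"CD4"`, `"CD8A"`).
#' @return a `subtype_assignment` data.frame (cell_id, label, rule) with
#'   one row per input cell.
#' @export
classify_t_cells <- function(matrix, threshold = 1,
                             cd4_gene = "CD4", cd8_gene = "CD8A") {
  need_markers(matrix, c(cd4_gene, cd8_gene))
  cd4 <- em_values(matrix)[cd4_gene, ]
  cd8 <- em_values(matrix)[cd8_gene, ]
  label <- rep("unassigned", ncol(matrix))
  label[cd4 > threshold & cd8 < threshold] <- "CD4"
  label[cd4 < threshold & cd8 > threshold] <- "CD8"
  label[cd4 > threshold & cd8 > threshold] <- "excluded"
  rule <- sprintf("%s=%.3g,%s=%.3g,thr=%g", cd4_gene, cd4, cd8_gene, cd8,
                  threshold)
  subtype_assignment(colnames(matrix), label, rule)
}

#' Classify CD4+ T cells into Tregs and T helper cells
#'
#' CD4+ cells whose summed FOXP3 and CD25 expression exceeds
#' `sum_threshold` are regulatory T cells (Treg); cells with both markers
#' exactly zero are T helper cells (Th); anything between is `unassigned`.
#' CD25 is accepted under either its protein name or the gene symbol
#' IL2RA, whichever is present in the matrix.
#'
#' @param matrix an [expression_matrix()] (log2(TPM + 1)).
#' @param cd4_cells character vector of CD4+ cell ids (e.g. from
#'   [classify_t_cells()]).
#' @param sum_threshold Treg cutoff on FOXP3 + CD25 (default 2).
#' @param foxp3_gene FOXP3 gene id.
#' @param cd25_genes accepted CD25 synonyms, first match used.
#' @return a `subtype_assignment` data.frame over `cd4_cells`.
#' @export
classify_cd4_subsets <- function(matrix, cd4_cells, sum_threshold = 2,
                                 foxp3_gene = "FOXP3",
                                 cd25_genes = c("CD25", "IL2RA")) {
  cd25_gene <- intersect(cd25_genes, rownames(matrix))[1]
  if (is.na(cd25_gene))
    stop("marker gene absent: none of ", paste(cd25_genes, collapse = "/"))
  need_markers(matrix, foxp3_gene)
  missing <- setdiff(cd4_cells, colnames(matrix))
  if (length(missing))
    stop("cells not in matrix: ", paste(missing, collapse = ", "))
  fox <- em_values(matrix)[foxp3_gene, cd4_cells]
  cd25 <- em_values(matrix)[cd25_gene, cd4_cells]
  label <- rep("unassigned", length(cd4_cells))
  label[fox + cd25 > sum_threshold] <- "Treg"
  label[fox == 0 & cd25 == 0] <- "Th"
  rule <- sprintf("%s=%.3g,%s=%.3g,thr=%g", foxp3_gene, fox, cd25_gene,
                  cd25, sum_threshold)
  subtype_assignment(cd4_cells, label, rule)
}

#' Classify fibroblasts into CAFs and myofibroblasts
#'
#' Cells with both FOS and VIM below 1 are excluded as low-quality or
#' non-fibroblast; the remaining cells are k-means clustered (k = 2,
#' multiple restarts under a fixed seed) on a marker-gene expression
#' panel. The cluster with the higher mean expression of the designated
#' CAF markers is labeled CAF, the other myofibroblast, so the labeling is
#' independent of arbitrary cluster indices.
#'
#' @param matrix an [expression_matrix()] of fibroblasts (log2(TPM + 1)).
#' @param marker_genes marker panel for clustering; default
#'   [default_fibroblast_markers()] (all markers).
#' @param caf_markers subset of markers defining the CAF direction;
#'   default the `caf` element of [default_fibroblast_markers()].
#' @param seed RNG seed for the k-means restarts.
#' @param k number of clusters (default 2).
#' @param exclusion_genes,exclusion_threshold the low-expression exclusion
#'   rule: cells with all `exclusion_genes` below the threshold are
#'   excluded (defaults FOS and VIM below 1).
#' @param nstart k-means restarts (default 10).
#' @return a `subtype_assignment` data.frame over all input cells.
#' @export
classify_fibroblasts <- function(matrix,
                                 marker_genes = NULL,
                                 caf_markers = NULL,
                                 seed = 1, k = 2,
                                 exclusion_genes = c("FOS", "VIM"),
                                 exclusion_threshold = 1,
                                 nstart = 10) {
  defaults <- default_fibroblast_markers()
  if (is.null(marker_genes))
    marker_genes <- unlist(defaults, use.names = FALSE)
  if (is.null(caf_markers)) caf_markers <- defaults$caf
  marker_genes <- intersect(marker_genes, rownames(matrix))
  caf_markers <- intersect(caf_markers, marker_genes)
  if (!length(marker_genes)) stop("no marker genes present in matrix")
  if (!length(caf_markers)) stop("no CAF markers present in matrix")
  need_markers(matrix, exclusion_genes)

  x <- em_values(matrix)
  excl <- colSums(x[exclusion_genes, , drop = FALSE] >=
                    exclusion_threshold) == 0
  if (all(excl)) stop("all cells excluded by the FOS/VIM rule")
  kept <- which(!excl)
  if (length(kept) < 2 * k)
    stop("too few cells after exclusion for k-means (need >= ", 2 * k, ")")

  sub <- t(x[marker_genes, kept, drop = FALSE])
  set.seed(seed)
  km <- stats::kmeans(sub, centers = k, nstart = nstart)
  caf_mean <- vapply(seq_len(k), function(cl) {
    mean(x[caf_markers, kept[km$cluster == cl], drop = FALSE])
  }, numeric(1))
  caf_cluster <- which.max(caf_mean)

  label <- rep("excluded", ncol(x))
  label[kept] <- ifelse(km$cluster == caf_cluster, "CAF", "myofibroblast")
  rule <- rep("FOS/VIM exclusion", ncol(x))
  rule[kept] <- sprintf("kmeans cluster %d (caf_cluster=%d)", km$cluster,
                        caf_cluster)
  subtype_assignment(colnames(x), label, rule)
}

#' Default fibroblast marker panel
#'
#' A synthetic curation of canonical cancer-associated-fibroblast markers
#' (matrix remodeling and activation genes) versus myofibroblast markers
#' (smooth-muscle contractile genes), intended as an overridable default
#' for [classify_fibroblasts()].
#'
#' @return list with character vectors `caf` and `myofibroblast`.
#' @export
default_fibroblast_markers <- function() {
  list(
    caf = c("FAP", "THY1", "PDPN", "PDGFRA", "PDGFRL", "MMP2", "DCN",
            "COL1A1", "COL1A2", "COL3A1"),
    myofibroblast = c("ACTA2", "MYL9", "MYLK", "TAGLN", "MCAM")
  )
}

subtype_assignment <- function(cell_id, label, rule) {
  structure(
    data.frame(cell_id = cell_id, label = label, rule = rule,
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("subtype_assignment", "data.frame"))
}

need_markers <- function(matrix, genes) {
  missing <- setdiff(genes, rownames(matrix))
  if (length(missing))
    stop("marker gene absent: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}
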