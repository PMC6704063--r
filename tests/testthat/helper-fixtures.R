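# Small in-code fixtures and independent oracles shared across tests.

toy_matrix <- function(values, genes = NULL, cells = NULL,
                       unit = "log2tpm1") {
  if (is.null(genes))
    genes <- if (!is.null(rownames(values))) rownames(values) else
      sprintf("g%d", seq_len(nrow(values)))
  if (is.null(cells))
    cells <- if (!is.null(colnames(values))) colnames(values) else
      sprintf("c%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, cells)
  expression_matrix(values, unit = unit)
}

toy_annotation <- function(cells, cell_type, tumor_id = "t1",
                           malignant = FALSE) {
  data.frame(cell_id = cells, tumor_id = tumor_id, cell_type = cell_type,
             malignant = malignant, stringsAsFactors = FALSE)
}

random_matrix <- function(n_genes, n_cells, unit = "log2tpm1",
                          lambda = 3) {
  toy_matrix(matrix(stats::rpois(n_genes * n_cells, lambda) +
                      stats::runif(n_genes * n_cells),
                    n_genes, n_cells), unit = unit)
}

# independent brute-force GSEA running-sum walk (explicit loop,
# no shared code with enrichment_score)
brute_es <- function(genes, scores, set, p = 1) {
  hit <- genes %in% set
  nh <- sum(hit)
  sw <- sum(abs(scores[hit])^p)
  cur <- 0
  best <- 0
  for (i in seq_along(genes)) {
    if (hit[i]) {
      cur <- cur + if (sw > 0) abs(scores[i])^p / sw else 0
    } else {
      cur <- cur - 1 / (length(genes) - nh)
    }
    if (abs(cur) > abs(best)) best <- cur
  }
  best
}

# independent PCA-loading score via eigendecomposition of the covariance
pca_score_oracle <- function(x, threshold = 0.8) {
  ev <- eigen(stats::cov(t(x)), symmetric = TRUE)
  vals <- ev$values[ev$values > 1e-12 * max(ev$values)]
  k <- which(cumsum(vals) / sum(vals) >= threshold)[1]
  s <- rowSums(abs(ev$vectors[, seq_len(k), drop = FALSE]))
  stats::setNames(s, rownames(x))
}

# independent threshold-rule oracle for T-cell classification
t_cell_rule_oracle <- function(cd4, cd8a, thr = 1) {
  if (cd4 > thr && cd8a > thr) return("excluded")
  if (cd4 > thr && cd8a < thr) return("CD4")
  if (cd4 < thr && cd8a > thr) return("CD8")
  "unassigned"
}

treg_rule_oracle <- function(foxp3, cd25, thr = 2) {
  if (foxp3 + cd25 > thr) return("Treg")
  if (foxp3 == 0 && cd25 == 0) return("Th")
  "unassigned"
}
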