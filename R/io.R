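#' Read pipeline inputs
#'
#' Reads an expression matrix (TSV, or MatrixMarket triplet with side files),
#' a cell annotation table, gene sets in GMT format and, optionally, a gene
#' length table, and aligns them. Genes that appear in gene sets but not in
#' the matrix are dropped from the sets with a warning; sets emptied this way
#' are removed.
#'
#' The TSV matrix layout is: first column gene id, header row of cell ids.
#' The MTX layout follows the common 10x-style convention: `matrix.mtx` plus
#' `genes.tsv` and `barcodes.tsv` next to it (one id per line, first column
#' used).
#'
#' @param matrix_path path to the matrix TSV, or to a `.mtx` file.
#' @param annotation_path TSV with columns cell_id, tumor_id, cell_type,
#'   malignant.
#' @param gmt_path gene sets in GMT format.
#' @param lengths_path optional TSV: gene_id, length (bases).
#' @param unit expression unit of the matrix file.
#' @return list with elements `matrix` (`expr_matrix`), `annotation`
#'   (data.frame), `gene_sets` (`gene_sets`), `lengths` (named numeric or
#'   NULL) and `dropped_set_genes` (genes removed from sets).
#' @export
read_inputs <- function(matrix_path, annotation_path, gmt_path,
                        lengths_path = NULL,
                        unit = c("log2tpm1", "tpm", "counts")) {
  unit <- match.arg(unit)
  for (p in c(matrix_path, annotation_path, gmt_path, lengths_path))
    if (!file.exists(p)) stop("file not found: ", p)

  mat <- if (grepl("\\.mtx$", matrix_path)) {
    read_mtx_matrix(matrix_path)
  } else {
    read_tsv_matrix(matrix_path)
  }
  mat <- expression_matrix(mat, unit = unit)

  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  ann <- cell_annotation(ann, matrix = mat)

  gs <- read_gmt(gmt_path)
  all_genes <- rownames(mat)
  dropped <- setdiff(unique(unlist(gs)), all_genes)
  if (length(dropped)) {
    warning(length(dropped),
            " gene-set genes absent from the matrix were dropped from sets")
    gs2 <- lapply(gs, intersect, all_genes)
    gs2 <- gs2[lengths(gs2) > 0L]
    gs <- gene_set_collection(gs2, attr(gs, "categories")[names(gs2)])
  }

  lengths <- NULL
  if (!is.null(lengths_path)) {
    lt <- utils::read.delim(lengths_path, stringsAsFactors = FALSE)
    lengths <- gene_length_table(stats::setNames(lt[[2]], lt[[1]]))
  }

  list(matrix = mat, annotation = ann, gene_sets = gs,
       lengths = lengths, dropped_set_genes = dropped)
}

read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

read_mtx_matrix <- function(path) {
  dir <- dirname(path)
  gf <- file.path(dir, "genes.tsv")
  bf <- file.path(dir, "barcodes.tsv")
  if (!file.exists(gf) || !file.exists(bf))
    stop("MTX matrix requires genes.tsv and barcodes.tsv beside ", path)
  m <- as.matrix(Matrix::readMM(path))
  genes <- utils::read.delim(gf, header = FALSE, stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.delim(bf, header = FALSE, stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(genes) || ncol(m) != length(cells))
    stop("MTX dimensions do not match genes.tsv/barcodes.tsv")
  dimnames(m) <- list(genes, cells)
  m
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (set name, description, then member genes, tab
#'   separated).
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  gene_set_collection(sets)
}

#' Write gene sets in GMT format
#' @param sets a `gene_sets` object or named list.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Gene length table
#'
#' Per-gene transcript length in bases (for genes with several transcripts,
#' the longest is the conventional choice upstream of this package).
#'
#' @param lengths named numeric vector, names = gene ids, values > 0.
#' @return validated named numeric vector of class `gene_lengths`.
#' @export
gene_length_table <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("gene lengths must be named by gene id")
  if (anyDuplicated(names(lengths)))
    stop("duplicate gene ids in length table")
  lengths <- stats::setNames(as.numeric(lengths), names(lengths))
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("gene lengths must be positive")
  structure(lengths, class = c("gene_lengths", "numeric"))
}

#' Write an expression matrix as TSV
#' @param matrix `expr_matrix`.
#' @param path output path.
#' @param id_col name of the gene id column.
#' @export
write_tsv_matrix <- function(matrix, path, id_col = "gene") {
  df <- data.frame(rownames(matrix), em_values(matrix),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
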