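#' Expression matrix container
#'
#' A light wrapper around a numeric matrix (genes in rows, cells in columns)
#' carrying the expression unit. Three units are recognised:
#' `"log2tpm1"` (log2(TPM + 1), the working unit of the pipeline),
#' `"tpm"` (linear transcripts-per-million) and `"counts"`
#' (read counts or length-scaled pseudo-counts).
#'
#' @param values numeric matrix with unique, non-empty rownames (gene ids)
#'   and colnames (cell ids); all values must be non-negative and finite.
#' @param unit one of `"log2tpm1"`, `"tpm"`, `"counts"`.
#'
#' @return an `expr_matrix`: the matrix with a `unit` attribute.
#' @export
#'
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' em <- expression_matrix(m, unit = "counts")
#' em_unit(em)
expression_matrix <- function(values, unit = c("log2tpm1", "tpm", "counts")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs rownames (gene ids) and colnames (cell ids)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate cell ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (any(values < 0))
    stop("expression values must be non-negative")
  structure(values, unit = unit, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expression_matrix
#' @param x an `expr_matrix`.
#' @export
em_unit <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) stop("object has no expression unit; use expression_matrix()")
  u
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d cells [unit: %s]\n",
              nrow(x), ncol(x), em_unit(x)))
  n <- min(5L, nrow(x)); m <- min(5L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  invisible(x)
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out))
    out <- structure(out, unit = attr(x, "unit"),
                     class = c("expr_matrix", "matrix", "array"))
  out
}

# internal: strip class, keep plain matrix
em_values <- function(x) {
  y <- unclass(x)
  attr(y, "unit") <- NULL
  y
}

# internal: rebuild with same unit
em_like <- function(values, template, unit = em_unit(template)) {
  expression_matrix(values, unit = unit)
}

#' Cell annotation table
#'
#' Validates and normalises a per-cell annotation `data.frame` with columns
#' `cell_id`, `tumor_id`, `cell_type` and logical `malignant`.
#'
#' @param df data.frame with the four columns above.
#' @param matrix optional `expr_matrix`; when given, every cell of the matrix
#'   must appear exactly once in the annotation (extra annotated cells are
#'   dropped with a message) and rows are reordered to the matrix columns.
#' @return a validated data.frame.
#' @export
cell_annotation <- function(df, matrix = NULL) {
  need <- c("cell_id", "tumor_id", "cell_type", "malignant")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation is missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need]
  df$cell_id <- as.character(df$cell_id)
  df$tumor_id <- as.character(df$tumor_id)
  df$cell_type <- as.character(df$cell_type)
  df$malignant <- as.logical(df$malignant)
  if (anyDuplicated(df$cell_id))
    stop("duplicate cell ids in annotation: ",
         paste(unique(df$cell_id[duplicated(df$cell_id)]), collapse = ", "))
  if (any(!nzchar(df$cell_type)) || anyNA(df$cell_type))
    stop("cell_type must be non-empty for every cell")
  if (anyNA(df$malignant))
    stop("malignant flag must be TRUE/FALSE for every cell")
  if (!is.null(matrix)) {
    cells <- colnames(matrix)
    absent <- setdiff(cells, df$cell_id)
    if (length(absent))
      stop("cells present in matrix but not in annotation: ",
           paste(absent, collapse = ", "))
    extra <- setdiff(df$cell_id, cells)
    if (length(extra))
      message(length(extra), " annotated cells absent from matrix were dropped")
    df <- df[match(cells, df$cell_id), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Gene set collection
#'
#' A named list of character vectors of gene ids, with an optional
#' category label per set (e.g. the KEGG metabolic categories).
#'
#' @param sets named list of character vectors; names unique, no empty set.
#' @param categories optional named character vector, `names(categories)`
#'   a subset of `names(sets)`.
#' @return a `gene_sets` object (the list, with a `categories` attribute).
#' @export
gene_set_collection <- function(sets, categories = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("'sets' must be a named list of gene id vectors")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene set names")
  if (any(lengths(sets) == 0L))
    stop("empty gene sets: ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (!is.null(categories)) {
    unknown <- setdiff(names(categories), names(sets))
    if (length(unknown))
      stop("categories refer to unknown sets: ", paste(unknown, collapse = ", "))
  }
  structure(sets, categories = categories, class = c("gene_sets", "list"))
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene_sets: %d sets, %d distinct genes\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}
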