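#' Construct a cells-by-genes count matrix
#'
#' A `count_matrix` holds raw non-negative integer counts with cells as
#' rows and genes as columns, together with unique cell and gene
#' identifiers. The values may be a base dense matrix or a sparse
#' `Matrix::dgCMatrix`; all downstream operations accept both.
#'
#' @param values numeric matrix (dense or sparse) of non-negative
#'   integer counts, cells x genes.
#' @param cell_ids character vector of unique cell identifiers, one per
#'   row. Defaults to existing rownames, or `cell_1..cell_n`.
#' @param gene_ids character vector of unique gene identifiers, one per
#'   column. Defaults to existing colnames, or `gene_1..gene_p`.
#' @return An object of class `count_matrix` with elements `values`,
#'   `cell_ids`, `gene_ids`.
#' @examples
#' m <- count_matrix(matrix(rpois(12, 3), 4, 3))
#' dim(m)
#' @export
count_matrix <- function(values, cell_ids = NULL, gene_ids = NULL) {
  if (!(is.matrix(values) || inherits(values, "Matrix")))
    stop("`values` must be a matrix or Matrix", call. = FALSE)
  if (is.null(cell_ids)) {
    cell_ids <- rownames(values)
    if (is.null(cell_ids))
      cell_ids <- sprintf("cell_%d", seq_len(nrow(values)))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values)
    if (is.null(gene_ids))
      gene_ids <- sprintf("gene_%d", seq_len(ncol(values)))
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values))
    stop("length(cell_ids) != number of rows", call. = FALSE)
  if (length(gene_ids) != ncol(values))
    stop("length(gene_ids) != number of columns", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicate cell identifiers", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers", call. = FALSE)
  mn <- suppressWarnings(min(values))
  if (is.finite(mn) && mn < 0)
    stop("counts must be non-negative", call. = FALSE)
  v <- as_numeric_values(values)
  if (any(abs(v - round(v)) > 1e-8))
    stop("counts must be integers", call. = FALSE)
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids),
            class = "count_matrix")
}

# non-zero entries (sparse) or all entries (dense) as a plain numeric vector
as_numeric_values <- function(values) {
  if (inherits(values, "sparseMatrix")) {
    as.numeric(Matrix::drop0(values)@x)
  } else {
    as.numeric(values)
  }
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes (%s storage)\n",
              nrow(x$values), ncol(x$values),
              if (inherits(x$values, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

#' Construct a normalized log-expression matrix
#'
#' An `expression_matrix` holds real-valued normalized log-expression
#' (cells x genes) plus a provenance record of the filters and
#' normalization that produced it.
#'
#' @param values numeric matrix, cells x genes, all finite.
#' @param cell_ids,gene_ids identifiers as in [count_matrix()].
#' @param provenance list recording processing steps (may be empty).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, cell_ids = NULL, gene_ids = NULL,
                              provenance = list()) {
  if (!(is.matrix(values) || inherits(values, "Matrix")))
    stop("`values` must be a matrix or Matrix", call. = FALSE)
  if (is.null(cell_ids)) {
    cell_ids <- rownames(values)
    if (is.null(cell_ids))
      cell_ids <- sprintf("cell_%d", seq_len(nrow(values)))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values)
    if (is.null(gene_ids))
      gene_ids <- sprintf("gene_%d", seq_len(ncol(values)))
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values) || length(gene_ids) != ncol(values))
    stop("identifier lengths do not match matrix shape", call. = FALSE)
  if (anyDuplicated(cell_ids) || anyDuplicated(gene_ids))
    stop("duplicate identifiers", call. = FALSE)
  v <- as_numeric_values(values)
  if (length(v) && !all(is.finite(v)))
    stop("expression values must be finite", call. = FALSE)
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
                 provenance = provenance),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cells x %d genes\n",
              nrow(x$values), ncol(x$values)))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  invisible(x)
}

# dense numeric matrix view of either container
dense_values <- function(x) {
  v <- if (inherits(x, c("count_matrix", "expression_matrix"))) x$values else x
  as.matrix(v)
}
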