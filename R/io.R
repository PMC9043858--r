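#' Read a count matrix from disk
#'
#' Dense `csv`/`tsv`: header row of gene names, first column of cell
#' barcodes, cells as rows. `mtx_dir`: a directory holding
#' `matrix.mtx`, `genes.tsv` and `barcodes.tsv` in the 10x convention
#' (gene-major MatrixMarket coordinates, transposed to cells x genes on
#' load). Non-integer entries are rejected with their coordinates.
#'
#' @param path file (csv/tsv) or directory (mtx_dir).
#' @param format `"csv"`, `"tsv"`, or `"mtx_dir"`.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, format = c("csv", "tsv", "mtx_dir")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("path does not exist: ", path, call. = FALSE)
  if (format == "mtx_dir") {
    read_counts_mtx_dir(path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("malformed header: need cell id column plus genes",
                           call. = FALSE)
    cell_ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    bad <- which(!is.finite(m) | m < 0 | abs(m - round(m)) > 1e-8,
                 arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-integer count at cell row %d, gene column %d",
                   bad[1, 1], bad[1, 2]), call. = FALSE)
    count_matrix(m, cell_ids, colnames(df)[-1])
  }
}

read_counts_mtx_dir <- function(path) {
  mtx <- file.path(path, "matrix.mtx")
  genes_f <- file.path(path, "genes.tsv")
  barcodes_f <- file.path(path, "barcodes.tsv")
  for (f in c(mtx, genes_f, barcodes_f))
    if (!file.exists(f)) stop("missing file in mtx directory: ", f,
                              call. = FALSE)
  lines <- readLines(mtx)
  body <- lines[!startsWith(lines, "%") & nzchar(trimws(lines))]
  if (length(body) < 1)
    stop("malformed MatrixMarket file '", mtx, "': no header line",
         call. = FALSE)
  hdr <- suppressWarnings(as.numeric(strsplit(trimws(body[1]), "\\s+")[[1]]))
  if (length(hdr) != 3 || anyNA(hdr))
    stop("malformed MatrixMarket file '", mtx, "': bad size header",
         call. = FALSE)
  if (length(body) - 1 != hdr[3])
    stop(sprintf(
      "malformed MatrixMarket file '%s': header declares %d entries but %d found",
      mtx, hdr[3], length(body) - 1), call. = FALSE)
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop("malformed MatrixMarket file '",
                                         mtx, "': ", conditionMessage(e),
                                         call. = FALSE))
  genes <- utils::read.table(genes_f, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  barcodes <- utils::read.table(barcodes_f, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(genes))
    stop(sprintf("MTX rows (%d) do not match genes.tsv entries (%d)",
                 nrow(m), length(genes)), call. = FALSE)
  if (ncol(m) != length(barcodes))
    stop(sprintf("MTX columns (%d) do not match barcodes.tsv entries (%d)",
                 ncol(m), length(barcodes)), call. = FALSE)
  x <- if (methods::is(m, "sparseMatrix")) m@x else as.numeric(m)
  if (length(x) && any(abs(x - round(x)) > 1e-8))
    stop("non-integer entries in MTX matrix", call. = FALSE)
  count_matrix(Matrix::t(m), barcodes, genes) # 10x gene-major -> cells x genes
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()]; `mtx_dir` creates the directory and
#' writes `matrix.mtx` (gene-major) with `genes.tsv`/`barcodes.tsv`
#' sidecars.
#'
#' @param counts a [count_matrix()].
#' @param path output file or directory.
#' @param format `"csv"`, `"tsv"`, or `"mtx_dir"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("csv", "tsv", "mtx_dir")) {
  format <- match.arg(format)
  stopifnot(inherits(counts, "count_matrix"))
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    m <- methods::as(methods::as(Matrix::t(counts$values), "CsparseMatrix"),
                     "generalMatrix")
    Matrix::writeMM(m, file.path(path, "matrix.mtx"))
    writeLines(counts$gene_ids, file.path(path, "genes.tsv"))
    writeLines(counts$cell_ids, file.path(path, "barcodes.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(cell_id = counts$cell_ids,
                     as.matrix(counts$values), check.names = FALSE)
    colnames(df) <- c("cell_id", counts$gene_ids)
    utils::write.table(df, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read a per-cell label file
#'
#' Two-column TSV (`cell_id`, `label`); a header line is auto-detected
#' by testing whether the first field matches a known cell id. Labels
#' are returned in the order of `cell_ids`; cells without labels and
#' label rows without matching cells are reported.
#'
#' @param path TSV path.
#' @param cell_ids cell identifiers defining the output order.
#' @return Character vector of labels, named by cell id, aligned to the
#'   labeled subset of `cell_ids`.
#' @export
read_labels <- function(path, cell_ids) {
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  df <- tryCatch(utils::read.table(path, sep = "\t", header = FALSE,
                                   stringsAsFactors = FALSE),
                 error = function(e) stop("empty or malformed label file: ",
                                          path, call. = FALSE))
  if (ncol(df) < 2) stop("label file needs two tab-separated columns",
                         call. = FALSE)
  # header present iff the first field is not a known cell id
  if (!(df[1, 1] %in% cell_ids)) df <- df[-1, , drop = FALSE]
  if (nrow(df) == 0) stop("label file contains no data rows", call. = FALSE)
  ids <- as.character(df[[1]])
  labels <- as.character(df[[2]])
  if (anyDuplicated(ids))
    stop("duplicate cell ids in label file: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(ids, cell_ids)
  if (length(unknown) == length(ids))
    stop("no label-file cell ids overlap the count matrix", call. = FALSE)
  if (length(unknown))
    warning("label file cells not in matrix (excluded): ",
            paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  keep <- intersect(cell_ids, ids)
  unlabeled <- setdiff(cell_ids, ids)
  if (length(unlabeled))
    warning(length(unlabeled), " matrix cell(s) have no label", call. = FALSE)
  out <- labels[match(keep, ids)]
  names(out) <- keep
  out
}

#' Write predictions or labels as a two-column TSV
#'
#' @param labels character vector named by cell id (or unnamed, with
#'   `cell_ids` supplied).
#' @param path output path.
#' @param cell_ids optional explicit identifiers.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, cell_ids = names(labels)) {
  stopifnot(!is.null(cell_ids), length(cell_ids) == length(labels))
  utils::write.table(data.frame(cell_id = cell_ids, label = labels),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a processed expression matrix as TSV
#'
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(cell_id = expr$cell_ids, as.matrix(expr$values),
                   check.names = FALSE)
  colnames(df) <- c("cell_id", expr$gene_ids)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression()]
#'
#' @param path TSV path.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  expression_matrix(m, as.character(df[[1]]), colnames(df)[-1])
}

#' Serialize a trained cell-type model to JSON
#'
#' Versioned schema holding the shared weights, task offsets,
#' intercepts, feature scaler, configuration and class map at full
#' precision.
#'
#' @param model a `celltyper_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_celltyper <- function(model, path) {
  stopifnot(inherits(model, "celltyper_model"))
  m <- model$model
  payload <- list(schema_version = 1L,
                  W0 = m$W0,
                  V = m$V,
                  intercepts = m$intercepts,
                  scaler = m$scaler,
                  config = unclass(m$config),
                  task_names = m$task_names,
                  n_features = m$n_features,
                  objective_trace = m$objective_trace,
                  n_iter = m$n_iter,
                  converged = m$converged,
                  class_map = model$class_map,
                  gene_ids = model$gene_ids)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a cell-type model saved by [save_celltyper()]
#'
#' @param path JSON path.
#' @return A `celltyper_model`.
#' @export
load_celltyper <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$schema_version) || p$schema_version != 1L)
    stop("unsupported model schema version", call. = FALSE)
  cfg <- p$config
  config <- rmtl_config(loss = cfg$loss, regularizer = cfg$regularizer,
                        lambda1 = cfg$lambda1, lambda2 = cfg$lambda2,
                        max_iter = cfg$max_iter, tol = cfg$tol,
                        step_init = cfg$step_init, seed = cfg$seed,
                        standardize = cfg$standardize,
                        fit_intercept = cfg$fit_intercept)
  V <- as.matrix(p$V)
  rownames(V) <- p$task_names
  W <- sweep(V, 2, p$W0, `+`)
  rownames(W) <- p$task_names
  scaler <- if (is.null(p$scaler)) NULL else
    list(center = as.numeric(p$scaler$center),
         scale = as.numeric(p$scaler$scale))
  m <- structure(list(W0 = as.numeric(p$W0), V = V,
                      intercepts = as.numeric(p$intercepts), W = W,
                      scaler = scaler, config = config,
                      objective_trace = as.numeric(p$objective_trace),
                      n_iter = p$n_iter, converged = p$converged,
                      task_names = p$task_names,
                      n_features = p$n_features),
                 class = "rmtl_model")
  structure(list(model = m, class_map = p$class_map,
                 gene_ids = p$gene_ids),
            class = "celltyper_model")
}
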