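#' Bundle an expression matrix with per-cell class labels
#'
#' @param expr an [expression_matrix()].
#' @param labels character vector of class names aligned to the cell
#'   order of `expr`.
#' @return Object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(expr, labels) {
  stopifnot(inherits(expr, "expression_matrix"))
  labels <- as.character(labels)
  if (length(labels) != nrow(expr$values))
    stop("label vector length does not match cell count", call. = FALSE)
  structure(list(expr = expr, labels = labels), class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d cells x %d genes, %d classes\n",
              nrow(x$expr$values), ncol(x$expr$values),
              length(unique(x$labels))))
  invisible(x)
}

#' Build one-vs-rest binary tasks from a labeled dataset
#'
#' One task per cell type: task `t` labels the cells of class `t` as
#' `+1` and all other cells as `-1`. All tasks share the full design
#' matrix, and every cell is positive in exactly one task. Class names
#' are ordered lexicographically so the task index <-> class name map
#' is reproducible.
#'
#' @param data a [labeled_dataset()] with at least two classes.
#' @return List with `tasks` (list of [task_data()]) and `class_map`
#'   (character vector; element `t` is the class of task `t`).
#' @export
build_tasks <- function(data) {
  stopifnot(inherits(data, "labeled_dataset"))
  classes <- sort(unique(data$labels))
  if (length(classes) < 2L)
    stop("one-vs-rest undefined with a single class", call. = FALSE)
  X <- dense_values(data$expr)
  tasks <- lapply(classes, function(cls) {
    y <- ifelse(data$labels == cls, 1, -1)
    task_data(X, y, task_name = cls)
  })
  list(tasks = tasks, class_map = classes)
}

#' Train an RMTL cell-type classifier
#'
#' Composition of [build_tasks()] and [rmtl_fit()]: builds one binary
#' one-vs-rest task per cell type and fits them jointly.
#'
#' @param data a [labeled_dataset()].
#' @param config an [rmtl_config()].
#' @return Object of class `celltyper_model`: the fitted `rmtl_model`
#'   plus `class_map` and the training gene identifiers.
#' @export
train_celltyper <- function(data, config = rmtl_config()) {
  built <- build_tasks(data)
  model <- rmtl_fit(built$tasks, config)
  structure(list(model = model, class_map = built$class_map,
                 gene_ids = data$expr$gene_ids),
            class = "celltyper_model")
}

#' @export
print.celltyper_model <- function(x, ...) {
  cat(sprintf("celltyper_model: %d cell types over %d genes\n",
              length(x$class_map), length(x$gene_ids)))
  print(x$model)
  invisible(x)
}

#' Align a query expression matrix to a model's gene space
#'
#' Reorders query columns to the training gene order; genes absent from
#' the query are imputed as zero (on the log scale) with a warning, and
#' extra query genes are dropped.
#'
#' @param model_genes character vector of training gene identifiers.
#' @param query an [expression_matrix()].
#' @return An [expression_matrix()] with columns exactly `model_genes`.
#' @export
align_genes <- function(model_genes, query) {
  stopifnot(inherits(query, "expression_matrix"))
  hit <- model_genes %in% query$gene_ids
  if (!any(hit))
    stop("no overlap between model genes and query genes", call. = FALSE)
  n_missing <- sum(!hit)
  if (n_missing > 0)
    warning(sprintf("%d of %d model genes missing from query; imputed as 0",
                    n_missing, length(model_genes)), call. = FALSE)
  qv <- dense_values(query)
  out <- matrix(0, nrow = nrow(qv), ncol = length(model_genes),
                dimnames = list(query$cell_ids, model_genes))
  out[, model_genes[hit]] <- qv[, model_genes[hit], drop = FALSE]
  expression_matrix(out, query$cell_ids, model_genes,
                    provenance = c(query$provenance,
                                   list(aligned_missing_genes = n_missing)))
}

#' Predict cell types for a query expression matrix
#'
#' Scores every cell under every task and assigns the class with the
#' maximal decision score; exact ties go to the lowest task index
#' (lexicographically first class).
#'
#' @param object a `celltyper_model` from [train_celltyper()].
#' @param expr an [expression_matrix()]; its gene set is aligned to the
#'   training genes via [align_genes()].
#' @param ... unused.
#' @return Character vector of predicted class names, named by cell id.
#' @export
predict.celltyper_model <- function(object, expr, ...) {
  aligned <- align_genes(object$gene_ids, expr)
  sc <- predict_scores(object$model, dense_values(aligned))
  idx <- apply(sc, 1, which.max) # which.max takes the first maximum: tie rule
  pred <- object$class_map[idx]
  names(pred) <- aligned$cell_ids
  pred
}
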