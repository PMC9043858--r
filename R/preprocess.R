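#' Quality-control thresholds for cell and gene filtering
#'
#' Thresholds for the two-stage filter used before normalization. A
#' cell is *good* when strictly more than `min_genes_per_good_cell`
#' genes have non-zero counts in it. A gene is *expressed* when its
#' count strictly exceeds `min_count_expressed` in at least a fraction
#' `min_fraction_good_cells` of the good cells (inclusive).
#'
#' @param min_genes_per_good_cell integer, default 1000. Strict `>`.
#' @param min_count_expressed integer, default 5. Strict `>`.
#' @param min_fraction_good_cells fraction in `[0,1]`, default 0.10.
#'   Inclusive `>=`.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes_per_good_cell = 1000,
                          min_count_expressed = 5,
                          min_fraction_good_cells = 0.10) {
  stopifnot(min_genes_per_good_cell >= 0,
            min_count_expressed >= 0,
            min_fraction_good_cells >= 0, min_fraction_good_cells <= 1)
  structure(list(min_genes_per_good_cell = as.integer(min_genes_per_good_cell),
                 min_count_expressed = as.integer(min_count_expressed),
                 min_fraction_good_cells = min_fraction_good_cells),
            class = "qc_thresholds")
}

#' Flag good cells
#'
#' A cell is good when the number of genes detected in it (count > 0)
#' strictly exceeds the threshold.
#'
#' @param counts a [count_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return Logical vector over cells, `TRUE` for good cells.
#' @export
identify_good_cells <- function(counts, thresholds = qc_thresholds()) {
  stopifnot(inherits(counts, "count_matrix"),
            inherits(thresholds, "qc_thresholds"))
  if (nrow(counts$values) == 0L || ncol(counts$values) == 0L)
    stop("count matrix has zero cells or zero genes", call. = FALSE)
  n_detected <- Matrix::rowSums(counts$values > 0)
  mask <- as.vector(n_detected) > thresholds$min_genes_per_good_cell
  names(mask) <- counts$cell_ids
  mask
}

#' Flag expressed genes over the good cells
#'
#' A gene is expressed when its count strictly exceeds
#' `min_count_expressed` in at least `min_fraction_good_cells` of the
#' good cells (inclusive fraction).
#'
#' @param counts a [count_matrix()].
#' @param good_mask logical mask over cells (from
#'   [identify_good_cells()]); must select at least one cell.
#' @param thresholds a [qc_thresholds()].
#' @return Logical vector over genes.
#' @export
identify_expressed_genes <- function(counts, good_mask,
                                     thresholds = qc_thresholds()) {
  stopifnot(inherits(counts, "count_matrix"),
            is.logical(good_mask), length(good_mask) == nrow(counts$values))
  n_good <- sum(good_mask)
  if (n_good == 0L)
    stop("no good cells: cannot evaluate expressed-gene fractions",
         call. = FALSE)
  sub <- counts$values[good_mask, , drop = FALSE]
  frac <- as.vector(Matrix::colSums(sub > thresholds$min_count_expressed)) / n_good
  mask <- frac >= thresholds$min_fraction_good_cells
  names(mask) <- counts$gene_ids
  mask
}

#' Normalize a filtered count matrix
#'
#' `library_size` rescales each cell so its total count equals the
#' median library size across cells; `none` returns the counts
#' unchanged. The normalization step is deliberately pluggable: any
#' external transformation producing a non-negative cells-by-genes
#' matrix can be substituted before [log_transform()].
#'
#' @param filtered a [count_matrix()] with no all-zero cells.
#' @param method `"library_size"` (default) or `"none"`.
#' @return Dense numeric matrix, same shape and dimnames as the input.
#' @export
normalize_counts <- function(filtered, method = c("library_size", "none")) {
  method <- match.arg(method)
  stopifnot(inherits(filtered, "count_matrix"))
  if (nrow(filtered$values) == 0L || ncol(filtered$values) == 0L)
    stop("empty matrix", call. = FALSE)
  m <- dense_values(filtered)
  if (method == "none") return(m)
  lib <- rowSums(m)
  if (any(lib == 0))
    stop("cell(s) with zero total count cannot be library-size normalized: ",
         paste(utils::head(filtered$cell_ids[lib == 0], 5), collapse = ", "),
         call. = FALSE)
  target <- stats::median(lib)
  m * (target / lib)
}

#' Log2 transform with pseudocount one
#'
#' Replaces each entry `x` by `log2(x + 1)`, mapping zero to zero.
#'
#' @param m numeric matrix with non-negative entries.
#' @return Matrix of the same shape.
#' @export
log_transform <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("negative entries cannot be log-transformed",
                       call. = FALSE)
  log2(m + 1)
}

#' Full preprocessing pipeline
#'
#' Applies, in order: the good-cell filter on the raw matrix, the
#' expressed-gene filter computed over good cells only, normalization,
#' and the log2(x+1) transform. The good-cell set is determined once
#' from the raw matrix and not recomputed after gene filtering.
#'
#' @param counts a [count_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @param method normalization method, see [normalize_counts()].
#' @return An [expression_matrix()] restricted to good cells and
#'   expressed genes; `provenance` records both masks and the method.
#' @export
preprocess_pipeline <- function(counts, thresholds = qc_thresholds(),
                                method = c("library_size", "none")) {
  method <- match.arg(method)
  good <- identify_good_cells(counts, thresholds)
  if (!any(good))
    stop("all cells filtered out by the good-cell rule", call. = FALSE)
  expressed <- identify_expressed_genes(counts, good, thresholds)
  if (!any(expressed))
    stop("all genes filtered out by the expressed-gene rule", call. = FALSE)
  sub <- count_matrix(counts$values[good, expressed, drop = FALSE],
                      counts$cell_ids[good], counts$gene_ids[expressed])
  norm <- normalize_counts(sub, method)
  vals <- log_transform(norm)
  expression_matrix(vals, sub$cell_ids, sub$gene_ids,
                    provenance = list(good_cells = good,
                                      expressed_genes = expressed,
                                      normalization = method,
                                      thresholds = unclass(thresholds),
                                      log = "log2(x+1)"))
}
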