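#' Configuration for the gamma-Poisson count simulator
#'
#' The generator follows the hierarchical skeleton of the Splat
#' simulation model: per-gene baseline means drawn from a gamma
#' distribution, multinomial group assignment, log-normal group-wise
#' differential-expression (DE) factors with random up/down direction,
#' log-normal cell library sizes, Poisson sampling of counts, and
#' logistic dropout whose midpoint is calibrated so the realized
#' extra-zero fraction matches `dropout_rate_target`. Batch effects and
#' mean-variance inflation are deliberately omitted.
#'
#' @param n_cells number of cells.
#' @param n_genes number of genes (default 2000).
#' @param n_groups number of cell groups (classes).
#' @param group_probs group probabilities (default equal); must sum
#'   to 1.
#' @param mean_shape,mean_rate gamma parameters of baseline gene means.
#' @param libsize_location,libsize_scale log-normal library-size
#'   parameters (natural-log scale).
#' @param de_prob fraction of genes DE in each group.
#' @param de_facLoc,de_facScale log-normal DE-factor parameters; larger
#'   `de_facLoc` means stronger group separation.
#' @param dropout_mid,dropout_shape logistic dropout parameters; the
#'   midpoint is recalibrated when `dropout_rate_target > 0`.
#' @param dropout_rate_target target fraction of observed non-zero
#'   counts zeroed by dropout (default 0.2); set to 0 to disable
#'   dropout entirely.
#' @param seed integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_cells, n_genes = 2000L, n_groups = 2L,
                       group_probs = NULL,
                       mean_shape = 0.6, mean_rate = 0.3,
                       libsize_location = 11, libsize_scale = 0.2,
                       de_prob = 0.1, de_facLoc = 0.1, de_facScale = 0.4,
                       dropout_mid = 0, dropout_shape = -1,
                       dropout_rate_target = 0.2, seed = 1L) {
  if (is.null(group_probs)) group_probs <- rep(1 / n_groups, n_groups)
  if (length(group_probs) != n_groups)
    stop("group_probs length must equal n_groups", call. = FALSE)
  if (any(group_probs < 0) || abs(sum(group_probs) - 1) > 1e-9)
    stop("group_probs must be non-negative and sum to 1", call. = FALSE)
  stopifnot(n_cells >= 1, n_genes >= 1, n_groups >= 1,
            mean_shape > 0, mean_rate > 0, libsize_scale >= 0,
            de_prob >= 0, de_prob <= 1, de_facScale >= 0,
            dropout_shape != 0,
            dropout_rate_target >= 0, dropout_rate_target < 1)
  structure(list(n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes),
                 n_groups = as.integer(n_groups),
                 group_probs = group_probs,
                 mean_shape = mean_shape, mean_rate = mean_rate,
                 libsize_location = libsize_location,
                 libsize_scale = libsize_scale,
                 de_prob = de_prob, de_facLoc = de_facLoc,
                 de_facScale = de_facScale,
                 dropout_mid = dropout_mid, dropout_shape = dropout_shape,
                 dropout_rate_target = dropout_rate_target,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Standard simulation presets
#'
#' Four benchmark configurations, all with 2,000 genes, equal group
#' probabilities and dropout rate 0.2: `data1` = 500 cells / 2 groups,
#' `data2` = 1,000 / 3, `data3` = 1,500 / 4, `data4` = 2,000 / 5.
#'
#' @param name one of `"data1"`, `"data2"`, `"data3"`, `"data4"`.
#' @param seed integer seed.
#' @param ... overrides passed on to [sim_config()] (e.g. `de_facLoc`).
#' @return A [sim_config()].
#' @export
sim_preset <- function(name, seed = 1L, ...) {
  presets <- list(data1 = c(cells = 500L, groups = 2L),
                  data2 = c(cells = 1000L, groups = 3L),
                  data3 = c(cells = 1500L, groups = 4L),
                  data4 = c(cells = 2000L, groups = 5L))
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  p <- presets[[name]]
  sim_config(n_cells = p[["cells"]], n_genes = 2000L,
             n_groups = p[["groups"]], dropout_rate_target = 0.2,
             seed = seed, ...)
}

# expected extra-zero fraction (among Poisson non-zeros) at midpoint `mid`
expected_extra_zero <- function(mid, shape, log_lambda, p_nonzero) {
  p_drop <- stats::plogis(shape * (log_lambda - mid))
  sum(p_drop * p_nonzero) / sum(p_nonzero)
}

# bisection for the dropout midpoint hitting the target extra-zero rate
calibrate_dropout_mid <- function(target, shape, lambda) {
  log_lambda <- log(lambda)
  p_nonzero <- 1 - exp(-lambda)
  lo <- min(log_lambda) - 25
  hi <- max(log_lambda) + 25
  f <- function(mid) expected_extra_zero(mid, shape, log_lambda, p_nonzero) -
    target
  # f is monotone in mid; direction depends on sign(shape)
  if (shape < 0) { a <- lo; b <- hi } else { a <- hi; b <- lo }
  fa <- f(a)
  if (fa > 0) return(a) # target below attainable range; best effort
  for (i in 1:100) {
    mid <- (a + b) / 2
    if (f(mid) <= 0) a <- mid else b <- mid
    if (abs(b - a) < 1e-10) break
  }
  (a + b) / 2
}

#' Simulate a grouped scRNA-seq count matrix
#'
#' Draws counts from the hierarchical gamma-Poisson model described in
#' [sim_config()] and returns them with ground-truth bookkeeping.
#'
#' @param config a [sim_config()].
#' @return Object of class `sim_result`: `counts` (a sparse
#'   [count_matrix()]), `labels` (group name per cell), and `truth`
#'   (baseline gene means, per-group DE factors, library sizes, Poisson
#'   rates summary, dropout midpoint, dropout mask as a sparse logical
#'   matrix, and the realized extra-zero fraction).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  res <- with_seed(config$seed, {
    ng <- config$n_genes
    nc <- config$n_cells
    nk <- config$n_groups
    base_means <- stats::rgamma(ng, shape = config$mean_shape,
                                rate = config$mean_rate)
    groups <- sample.int(nk, nc, replace = TRUE, prob = config$group_probs)
    de_factors <- matrix(1, nrow = ng, ncol = nk,
                         dimnames = list(NULL, paste0("group", seq_len(nk))))
    for (k in seq_len(nk)) {
      is_de <- stats::runif(ng) < config$de_prob
      n_de <- sum(is_de)
      if (n_de > 0) {
        fac <- stats::rlnorm(n_de, meanlog = config$de_facLoc,
                             sdlog = config$de_facScale)
        down <- stats::runif(n_de) < 0.5
        fac[down] <- 1 / fac[down]
        de_factors[is_de, k] <- fac
      }
    }
    group_means <- base_means * de_factors           # genes x groups
    group_props <- sweep(group_means, 2, colSums(group_means), `/`)
    lib_sizes <- stats::rlnorm(nc, meanlog = config$libsize_location,
                               sdlog = config$libsize_scale)
    lambda <- t(group_props[, groups, drop = FALSE]) * lib_sizes # cells x genes
    counts <- matrix(stats::rpois(length(lambda), as.vector(lambda)),
                     nrow = nc, ncol = ng)
    dropout_mid <- config$dropout_mid
    mask <- NULL
    realized <- 0
    if (config$dropout_rate_target > 0) {
      dropout_mid <- calibrate_dropout_mid(config$dropout_rate_target,
                                           config$dropout_shape, lambda)
      p_drop <- stats::plogis(config$dropout_shape *
                                (log(lambda) - dropout_mid))
      mask <- matrix(stats::runif(length(lambda)) < as.vector(p_drop),
                     nrow = nc, ncol = ng)
      realized <- sum(mask & counts > 0) / max(1, sum(counts > 0))
      counts[mask] <- 0L
    }
    list(counts = counts, groups = groups, base_means = base_means,
         de_factors = de_factors, lib_sizes = lib_sizes,
         dropout_mid = dropout_mid, mask = mask, realized = realized)
  })
  cell_ids <- sprintf("cell_%d", seq_len(config$n_cells))
  gene_ids <- sprintf("gene_%d", seq_len(config$n_genes))
  cm <- count_matrix(Matrix::Matrix(res$counts, sparse = TRUE),
                     cell_ids, gene_ids)
  labels <- paste0("group", res$groups)
  truth <- list(base_means = res$base_means,
                de_factors = res$de_factors,
                lib_sizes = res$lib_sizes,
                groups = res$groups,
                dropout_mid = res$dropout_mid,
                dropout_mask = if (is.null(res$mask)) NULL else
                  Matrix::Matrix(res$mask, sparse = TRUE),
                extra_zero_fraction = res$realized)
  structure(list(counts = cm, labels = labels, truth = truth,
                 config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "sim_result: %d cells x %d genes, %d groups, extra-zero fraction %.3f\n",
    x$config$n_cells, x$config$n_genes, x$config$n_groups,
    x$truth$extra_zero_fraction))
  invisible(x)
}
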