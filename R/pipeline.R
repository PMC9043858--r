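#' Run one stage of the cell-typing pipeline
#'
#' Thin programmatic umbrella over the package's modules, mirroring the
#' command-line interface. Every randomized stage consumes a seed
#' derived from `opts$seed` (the master seed) via [derive_seed()], so a
#' rerun with the same options reproduces the same artifacts byte for
#' byte.
#'
#' Options by command (all file outputs are plain text):
#' \describe{
#'   \item{simulate}{`preset` (or `n_cells`/`n_genes`/`n_groups` plus
#'     any [sim_config()] field), `out_counts` (MTX directory),
#'     `out_labels` (TSV), optional `out_truth` (JSON).}
#'   \item{preprocess}{`counts`, `counts_format`, `min_genes`,
#'     `min_count`, `min_frac`, `normalize`, `out` (expression TSV).}
#'   \item{train}{`expr`, `labels`, RMTL settings (`loss`,
#'     `regularizer`, `lambda1`, `lambda2`, `max_iter`, `tol`),
#'     `model_out` (JSON).}
#'   \item{predict}{`model`, `expr`, `out` (predictions TSV).}
#'   \item{evaluate}{`expr`, `labels`, `protocol` (`"subsample"` or
#'     `"cv"`), `runs`, `folds`, RMTL settings, `report` (JSON).}
#' }
#'
#' @param command one of `"simulate"`, `"preprocess"`, `"train"`,
#'   `"predict"`, `"evaluate"`.
#' @param opts named list of options; `opts$seed` defaults to 1.
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(command = c("simulate", "preprocess", "train",
                                     "predict", "evaluate"),
                         opts = list()) {
  command <- match.arg(command)
  seed <- if (is.null(opts$seed)) 1L else as.integer(opts$seed)
  t0 <- Sys.time()
  out <- switch(command,
    simulate = pipeline_simulate(opts, seed),
    preprocess = pipeline_preprocess(opts),
    train = pipeline_train(opts, seed),
    predict = pipeline_predict(opts),
    evaluate = pipeline_evaluate(opts, seed))
  message(sprintf("[scRMTL] %s finished in %.1fs (master seed %d)",
                  command, as.numeric(Sys.time() - t0, units = "secs"),
                  seed))
  invisible(out)
}

opt_or <- function(opts, name, default) {
  if (is.null(opts[[name]])) default else opts[[name]]
}

pipeline_simulate <- function(opts, seed) {
  cfg <- if (!is.null(opts$preset)) {
    sim_preset(opts$preset, seed = derive_seed(seed, "simulate"))
  } else {
    sim_config(n_cells = as.integer(opt_or(opts, "n_cells", 500L)),
               n_genes = as.integer(opt_or(opts, "n_genes", 2000L)),
               n_groups = as.integer(opt_or(opts, "n_groups", 2L)),
               de_prob = opt_or(opts, "de_prob", 0.1),
               de_facLoc = opt_or(opts, "de_facLoc", 0.1),
               de_facScale = opt_or(opts, "de_facScale", 0.4),
               dropout_rate_target = opt_or(opts, "dropout_rate", 0.2),
               seed = derive_seed(seed, "simulate"))
  }
  sim <- simulate_counts(cfg)
  out_counts <- opt_or(opts, "out_counts", "counts_mtx")
  write_counts(sim$counts, out_counts, format = "mtx_dir")
  out_labels <- opt_or(opts, "out_labels", "labels.tsv")
  write_labels(sim$labels, out_labels, cell_ids = sim$counts$cell_ids)
  paths <- list(counts = out_counts, labels = out_labels)
  if (!is.null(opts$out_truth)) {
    jsonlite::write_json(
      list(config = unclass(cfg),
           dropout_mid = sim$truth$dropout_mid,
           extra_zero_fraction = sim$truth$extra_zero_fraction,
           lib_sizes = sim$truth$lib_sizes,
           base_means = sim$truth$base_means,
           de_factors = as.data.frame(sim$truth$de_factors)),
      opts$out_truth, auto_unbox = TRUE, digits = NA)
    paths$truth <- opts$out_truth
  }
  paths
}

pipeline_preprocess <- function(opts) {
  counts <- read_counts(opts$counts,
                        format = opt_or(opts, "counts_format", "mtx_dir"))
  thr <- qc_thresholds(
    min_genes_per_good_cell = opt_or(opts, "min_genes", 1000L),
    min_count_expressed = opt_or(opts, "min_count", 5L),
    min_fraction_good_cells = opt_or(opts, "min_frac", 0.10))
  expr <- preprocess_pipeline(counts, thr,
                              method = opt_or(opts, "normalize",
                                              "library_size"))
  out <- opt_or(opts, "out", "expression.tsv")
  write_expression(expr, out)
  list(expression = out)
}

rmtl_config_from_opts <- function(opts, seed) {
  rmtl_config(loss = opt_or(opts, "loss", "logistic"),
              regularizer = opt_or(opts, "regularizer", "shared_offset"),
              lambda1 = opt_or(opts, "lambda1", 0.01),
              lambda2 = opt_or(opts, "lambda2", 0.01),
              max_iter = as.integer(opt_or(opts, "max_iter", 1000L)),
              tol = opt_or(opts, "tol", 1e-6),
              seed = derive_seed(seed, "rmtl"))
}

load_labeled <- function(opts) {
  expr <- read_expression(opts$expr)
  labels <- read_labels(opts$labels, expr$cell_ids)
  keep <- match(names(labels), expr$cell_ids)
  expr_sub <- expression_matrix(expr$values[keep, , drop = FALSE],
                                expr$cell_ids[keep], expr$gene_ids,
                                expr$provenance)
  labeled_dataset(expr_sub, unname(labels))
}

pipeline_train <- function(opts, seed) {
  data <- load_labeled(opts)
  cfg <- rmtl_config_from_opts(opts, seed)
  model <- train_celltyper(data, cfg)
  out <- opt_or(opts, "model_out", "model.json")
  save_celltyper(model, out)
  list(model = out)
}

pipeline_predict <- function(opts) {
  model <- load_celltyper(opts$model)
  expr <- read_expression(opts$expr)
  pred <- predict(model, expr)
  out <- opt_or(opts, "out", "predictions.tsv")
  write_labels(pred, out)
  list(predictions = out)
}

pipeline_evaluate <- function(opts, seed) {
  data <- load_labeled(opts)
  rmtl_cfg <- rmtl_config_from_opts(opts, seed)
  ecfg <- eval_config(
    n_runs = as.integer(opt_or(opts, "runs", 100L)),
    cv_folds = as.integer(opt_or(opts, "folds", 10L)),
    seed = derive_seed(seed, "evaluate"))
  protocol <- opt_or(opts, "protocol", "subsample")
  report <- if (protocol == "subsample") {
    res <- subsample_curve(data, ecfg, rmtl_cfg)
    list(protocol = "subsample",
         rates = ecfg$subsample_rates,
         mean_accuracy = res$summary$mean,
         sd_accuracy = res$summary$sd,
         accuracies = res$accuracies)
  } else if (protocol == "cv") {
    res <- cv_stability(data, ecfg, rmtl_cfg)
    list(protocol = "cv",
         validation = res$validation,
         test = res$test,
         fold_medians = res$fold_medians)
  } else stop("unknown protocol: ", protocol, call. = FALSE)
  report$effective_config <- list(eval = unclass(ecfg),
                                  rmtl = unclass(rmtl_cfg),
                                  master_seed = seed)
  out <- opt_or(opts, "report", "report.json")
  jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA)
  list(report = out)
}
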