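#' Evaluation protocol settings
#'
#' Defaults mirror the standard protocol: 80/20 train/test splits,
#' training-set subsampling at 20--100% in steps of 20%, 100 repeated
#' runs (scalable down), 10-fold cross-validation with 9:1 inner
#' train/validation splits.
#'
#' @param test_fraction held-out fraction per split, in (0,1).
#' @param subsample_rates ascending training-fraction grid in (0,1].
#' @param n_runs repeated runs per setting (>= 1).
#' @param cv_folds outer folds for [cv_stability()].
#' @param inner_train_fraction training share of each inner split.
#' @param seed master seed; all per-run seeds derive from it.
#' @return Object of class `eval_config`.
#' @export
eval_config <- function(test_fraction = 0.2,
                        subsample_rates = c(0.2, 0.4, 0.6, 0.8, 1.0),
                        n_runs = 100L, cv_folds = 10L,
                        inner_train_fraction = 0.9, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            all(subsample_rates > 0), all(subsample_rates <= 1),
            !is.unsorted(subsample_rates),
            n_runs >= 1, cv_folds >= 2,
            inner_train_fraction > 0, inner_train_fraction < 1)
  structure(list(test_fraction = test_fraction,
                 subsample_rates = subsample_rates,
                 n_runs = as.integer(n_runs),
                 cv_folds = as.integer(cv_folds),
                 inner_train_fraction = inner_train_fraction,
                 seed = as.integer(seed)),
            class = "eval_config")
}

# index split helper: returns test indices
draw_test_indices <- function(labels, test_fraction, seed, stratified) {
  n <- length(labels)
  with_seed(seed, {
    if (stratified) {
      test_idx <- integer(0)
      singletons <- character(0)
      for (cls in sort(unique(labels))) {
        idx <- which(labels == cls)
        n_test <- round(length(idx) * test_fraction)
        if (length(idx) == 1L && n_test == 0L)
          singletons <- c(singletons, cls)
        if (n_test > 0)
          test_idx <- c(test_idx, sample(idx, n_test))
      }
      if (length(singletons))
        warning("class(es) with a single cell kept entirely in training: ",
                paste(singletons, collapse = ", "), call. = FALSE)
      sort(test_idx)
    } else {
      sort(sample.int(n, round(n * test_fraction)))
    }
  })
}

subset_dataset <- function(data, idx) {
  labeled_dataset(
    expression_matrix(data$expr$values[idx, , drop = FALSE],
                      data$expr$cell_ids[idx], data$expr$gene_ids,
                      data$expr$provenance),
    data$labels[idx])
}

#' Split a labeled dataset into training and test parts
#'
#' Disjoint, exhaustive, seeded split; stratified by class by default
#' so rare cell types stay represented in both parts. A class with a
#' single cell goes to training with a warning.
#'
#' @param data a [labeled_dataset()].
#' @param test_fraction held-out fraction (default 0.2, the 8:2 split).
#' @param seed integer seed.
#' @param stratified stratify by class (default `TRUE`).
#' @return List with `train` and `test`, both [labeled_dataset()]s.
#' @export
split_train_test <- function(data, test_fraction = 0.2, seed = 1L,
                             stratified = TRUE) {
  stopifnot(inherits(data, "labeled_dataset"))
  n <- length(data$labels)
  test_idx <- draw_test_indices(data$labels, test_fraction, seed, stratified)
  if (length(test_idx) == 0L || length(test_idx) == n)
    stop("split left an empty part; not enough cells for test_fraction = ",
         test_fraction, call. = FALSE)
  train_idx <- setdiff(seq_len(n), test_idx)
  list(train = subset_dataset(data, train_idx),
       test = subset_dataset(data, test_idx))
}

# stratified subsample of a dataset to fraction `rate`, >= 1 cell per class
subsample_dataset <- function(data, rate, seed) {
  if (rate >= 1) return(data)
  idx <- with_seed(seed, {
    keep <- integer(0)
    for (cls in sort(unique(data$labels))) {
      cand <- which(data$labels == cls)
      n_keep <- max(1L, round(length(cand) * rate))
      keep <- c(keep, sample(cand, n_keep))
    }
    sort(keep)
  })
  subset_dataset(data, idx)
}

# held-out accuracy of a trained celltyper on a labeled dataset
heldout_accuracy <- function(model, data) {
  pred <- predict(model, data$expr)
  mean(pred == data$labels)
}

#' Training-size accuracy curve
#'
#' For every subsample rate and run: a fresh stratified 8:2 split, the
#' training set subsampled (stratified) to the rate, a model fit, and
#' the test accuracy recorded. Runs are independently seeded from the
#' master seed.
#'
#' @param data a [labeled_dataset()].
#' @param eval_cfg an [eval_config()].
#' @param rmtl_cfg an [rmtl_config()].
#' @return List with `summary` (data frame: rate, mean, sd over runs)
#'   and `accuracies` (matrix rates x runs).
#' @export
subsample_curve <- function(data, eval_cfg = eval_config(),
                            rmtl_cfg = rmtl_config()) {
  rates <- eval_cfg$subsample_rates
  acc <- matrix(NA_real_, nrow = length(rates), ncol = eval_cfg$n_runs,
                dimnames = list(paste0("rate_", rates), NULL))
  for (run in seq_len(eval_cfg$n_runs)) {
    for (ri in seq_along(rates)) {
      key <- sprintf("curve_r%g_run%d", rates[ri], run)
      sp <- split_train_test(data, eval_cfg$test_fraction,
                             seed = derive_seed(eval_cfg$seed, key))
      tr <- subsample_dataset(sp$train, rates[ri],
                              seed = derive_seed(eval_cfg$seed,
                                                 paste0(key, "_sub")))
      if (length(unique(tr$labels)) < 2L) {
        warning(sprintf("rate %g run %d: subsample lost all but one class; skipped",
                        rates[ri], run), call. = FALSE)
        next
      }
      fit <- train_celltyper(tr, rmtl_cfg)
      acc[ri, run] <- heldout_accuracy(fit, sp$test)
    }
  }
  summary <- data.frame(rate = rates,
                        mean = apply(acc, 1, mean, na.rm = TRUE),
                        sd = apply(acc, 1, stats::sd, na.rm = TRUE))
  list(summary = summary, accuracies = acc)
}

#' Per-class recall and precision
#'
#' Computes the confusion matrix and per-class recall
#' `TP / (TP + FN)` and precision `TP / (TP + FP)`. A class never
#' predicted gets `NA` precision (undefined), not an error.
#'
#' @param true_labels,predicted_labels equal-length character vectors.
#' @return List with `recall`, `precision` (named numeric vectors over
#'   the union of observed classes) and `confusion` (true x predicted
#'   table).
#' @export
class_metrics <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length", call. = FALSE)
  classes <- sort(union(unique(true_labels), unique(predicted_labels)))
  tl <- factor(true_labels, levels = classes)
  pl <- factor(predicted_labels, levels = classes)
  confusion <- table(true = tl, predicted = pl)
  tp <- diag(confusion)
  recall <- ifelse(rowSums(confusion) > 0, tp / rowSums(confusion), NA_real_)
  precision <- ifelse(colSums(confusion) > 0, tp / colSums(confusion),
                      NA_real_)
  names(recall) <- names(precision) <- classes
  list(recall = recall, precision = precision, confusion = confusion)
}

#' Cross-validation stability protocol
#'
#' Outer stratified k-fold partition. Within each fold's training
#' complement, `n_runs` seeded inner splits (train:validation at
#' `inner_train_fraction`, default 9:1) each yield a validation
#' accuracy; one model trained on the full complement yields the fold's
#' test accuracy. With `cv_folds = 10` and `n_runs = 100` this produces
#' 1,000 validation accuracies and 10 test accuracies.
#'
#' @param data a [labeled_dataset()].
#' @param eval_cfg an [eval_config()].
#' @param rmtl_cfg an [rmtl_config()].
#' @return List with `validation` (matrix folds x runs), `test` (vector
#'   over folds), and `fold_medians` (median validation accuracy per
#'   fold).
#' @export
cv_stability <- function(data, eval_cfg = eval_config(),
                         rmtl_cfg = rmtl_config()) {
  k <- eval_cfg$cv_folds
  folds <- stratified_fold_ids(data$labels, k,
                               seed = derive_seed(eval_cfg$seed, "outer_cv"))
  val <- matrix(NA_real_, nrow = k, ncol = eval_cfg$n_runs,
                dimnames = list(paste0("fold_", seq_len(k)), NULL))
  test <- numeric(k)
  for (f in seq_len(k)) {
    tr_data <- subset_dataset(data, which(folds != f))
    te_data <- subset_dataset(data, which(folds == f))
    for (run in seq_len(eval_cfg$n_runs)) {
      sp <- split_train_test(
        tr_data, test_fraction = 1 - eval_cfg$inner_train_fraction,
        seed = derive_seed(eval_cfg$seed, sprintf("cv_f%d_run%d", f, run)))
      fit <- train_celltyper(sp$train, rmtl_cfg)
      val[f, run] <- heldout_accuracy(fit, sp$test)
    }
    fit <- train_celltyper(tr_data, rmtl_cfg)
    test[f] <- heldout_accuracy(fit, te_data)
  }
  list(validation = val, test = test,
       fold_medians = apply(val, 1, stats::median))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of the rank-sum null distribution when the
#' combined sample size is at most 12 and there are no ties; otherwise
#' a normal approximation with tie correction. Two samples that are
#' identical constants yield `p = 1`.
#'
#' @param a,b non-empty numeric samples.
#' @param mode `"auto"` (default; dispatches as above), `"exact"`, or
#'   `"normal_approx"`.
#' @return Two-sided p-value in (0, 1].
#' @export
wilcoxon_rank_sum <- function(a, b, mode = c("auto", "exact",
                                             "normal_approx")) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be non-empty",
                                     call. = FALSE)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) return(1.0)
  has_ties <- anyDuplicated(pooled) > 0
  n <- length(pooled); na <- length(a)
  if (mode == "auto")
    mode <- if (n <= 12 && !has_ties) "exact" else "normal_approx"
  r <- rank(pooled)
  W <- sum(r[seq_len(na)])
  if (mode == "exact") {
    if (has_ties)
      stop("exact enumeration requires tie-free samples", call. = FALSE)
    mu <- na * (n + 1) / 2
    combos <- utils::combn(n, na)
    sums <- colSums(matrix(seq_len(n)[combos], nrow = na))
    p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
    min(1, p)
  } else {
    mu <- na * (n + 1) / 2
    nb <- n - na
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(1.0)
    z <- (W - mu) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}
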