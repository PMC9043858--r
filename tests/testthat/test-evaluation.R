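test_that("train/test split is a seeded stratified partition", {
  d <- toy_labeled(seed = 5, n_per = 50, p = 8, k = 2) # 100 cells
  sp <- split_train_test(d, 0.2, seed = 3)
  expect_equal(length(sp$train$labels), 80)
  expect_equal(length(sp$test$labels), 20)
  expect_setequal(c(sp$train$expr$cell_ids, sp$test$expr$cell_ids),
                  d$expr$cell_ids)
  expect_length(intersect(sp$train$expr$cell_ids, sp$test$expr$cell_ids), 0)
  # stratification keeps class balance in both parts
  expect_equal(unname(table(sp$test$labels)), c(10L, 10L), ignore_attr = TRUE)
  sp2 <- split_train_test(d, 0.2, seed = 3)
  expect_identical(sp$test$expr$cell_ids, sp2$test$expr$cell_ids)
  # a singleton class stays in training, with a warning
  d1 <- labeled_dataset(d$expr, c("solo", d$labels[-1]))
  expect_warning(sp3 <- split_train_test(d1, 0.2, seed = 1), "single cell")
  expect_true("solo" %in% sp3$train$labels)
  expect_false("solo" %in% sp3$test$labels)
})

test_that("subsample curve has one row per rate and n_runs columns", {
  d <- toy_labeled(seed = 6, n_per = 30, p = 10, k = 2)
  ec <- eval_config(subsample_rates = c(0.4, 1.0), n_runs = 3, seed = 2)
  rc <- rmtl_config(max_iter = 150)
  res <- subsample_curve(d, ec, rc)
  expect_equal(dim(res$accuracies), c(2L, 3L))
  expect_true(all(res$accuracies >= 0 & res$accuracies <= 1))
  expect_equal(nrow(res$summary), 2L)
  expect_equal(res$summary$mean,
               unname(rowMeans(res$accuracies)))
})

test_that("class metrics follow the confusion-matrix definitions", {
  perfect <- class_metrics(c("A", "B", "A"), c("A", "B", "A"))
  expect_true(all(perfect$recall == 1) && all(perfect$precision == 1))
  m <- class_metrics(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  expect_equal(unname(m$recall), c(0.5, 1.0))
  expect_equal(unname(m$precision), c(1.0, 2 / 3))
  # micro-averaged recall equals accuracy
  set.seed(8)
  true <- sample(letters[1:3], 60, replace = TRUE)
  pred <- sample(letters[1:3], 60, replace = TRUE)
  mm <- class_metrics(true, pred)
  micro <- sum(diag(mm$confusion)) / sum(mm$confusion)
  expect_equal(micro, mean(true == pred))
  # class never predicted: NA precision, not an error
  mp <- class_metrics(c("A", "B"), c("A", "A"))
  expect_true(is.na(mp$precision[["B"]]))
  expect_error(class_metrics(c("A"), c("A", "B")), "length")
})

test_that("cv stability yields folds x runs validation accuracies", {
  d <- toy_labeled(seed = 9, n_per = 30, p = 8, k = 2)
  ec <- eval_config(n_runs = 2, cv_folds = 3, seed = 4)
  res <- cv_stability(d, ec, rmtl_config(max_iter = 150))
  expect_equal(dim(res$validation), c(3L, 2L))
  expect_equal(sum(!is.na(res$validation)), 6L)
  expect_length(res$test, 3L)
  expect_length(res$fold_medians, 3L)
  expect_true(all(res$validation >= 0 & res$validation <= 1))
})

test_that("wilcoxon rank-sum: exact enumeration, ties, and invariances", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 1 / 3)
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5)), 1.0)
  # exact mode agrees with the reference implementation on tie-free input
  set.seed(10)
  for (r in 1:20) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    x <- sample(seq_len(50), na + nb) # distinct values, no ties
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    expect_equal(wilcoxon_rank_sum(a, b, mode = "exact"),
                 stats::wilcox.test(a, b, exact = TRUE)$p.value)
  }
  # invariance under a common monotone transform
  a <- c(0.1, 0.7, 0.4); b <- c(0.9, 0.2)
  expect_equal(wilcoxon_rank_sum(a, b), wilcoxon_rank_sum(exp(a), exp(b)))
  # tie-corrected normal approximation matches the reference formula
  a2 <- c(1, 2, 2, 3, 5, 6, 7); b2 <- c(2, 3, 3, 4, 8, 9)
  expect_equal(wilcoxon_rank_sum(a2, b2, mode = "normal_approx"),
               stats::wilcox.test(a2, b2, exact = FALSE,
                                  correct = FALSE)$p.value)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})
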