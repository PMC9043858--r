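test_that("good-cell rule uses a strict 'more than' threshold", {
  # 3 cells over 1200 genes: 1001, 1000 and 0 genes detected
  i <- c(rep(1L, 1001), rep(2L, 1000))
  j <- c(seq_len(1001), seq_len(1000))
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(3, 1200))
  cm <- count_matrix(m)
  mask <- identify_good_cells(cm, qc_thresholds())
  expect_identical(unname(mask), c(TRUE, FALSE, FALSE))
  # the all-zero cell is never good, even at threshold 0
  expect_false(identify_good_cells(cm, qc_thresholds(0))[[3]])
  expect_error(identify_good_cells(count_matrix(matrix(0, 0, 3)),
                                   qc_thresholds()), "zero cells")
})

test_that("expressed-gene rule: strict count, inclusive fraction", {
  cm <- toy_counts_6x3()
  good <- rep(TRUE, 6)
  mask <- identify_expressed_genes(cm, good, qc_thresholds())
  expect_identical(unname(mask), c(TRUE, FALSE, TRUE))
  # count 6 in exactly 10% of 100 good cells -> expressed (>= is inclusive)
  m <- matrix(0, 100, 2)
  m[1:10, 1] <- 6
  m[, 2] <- 5 # exactly 5 never exceeds 5
  cm2 <- count_matrix(m)
  mask2 <- identify_expressed_genes(cm2, rep(TRUE, 100), qc_thresholds())
  expect_identical(unname(mask2), c(TRUE, FALSE))
  expect_error(identify_expressed_genes(cm, rep(FALSE, 6), qc_thresholds()),
               "no good cells")
})

test_that("library-size normalization scales to the median library", {
  # cell totals 100 and 300, median 200 -> factors 2.0 and 2/3
  cm <- count_matrix(matrix(c(60, 40, 100, 200), nrow = 2, byrow = TRUE))
  out <- normalize_counts(cm, "library_size")
  expect_equal(rowSums(out), c(200, 200), ignore_attr = TRUE)
  expect_equal(out[1, ], c(60, 40) * 2.0, ignore_attr = TRUE)
  expect_equal(out[2, ], c(100, 200) * (2 / 3), ignore_attr = TRUE)
  # equal totals: identity
  eq <- count_matrix(matrix(c(1, 3, 2, 2), 2, byrow = TRUE))
  expect_equal(normalize_counts(eq, "library_size"),
               as.matrix(eq$values), ignore_attr = TRUE)
  # single cell: factor 1
  one <- count_matrix(matrix(c(5L, 7L), 1))
  expect_equal(normalize_counts(one, "library_size"),
               as.matrix(one$values), ignore_attr = TRUE)
  zero <- count_matrix(matrix(c(0, 0, 1, 2), 2, byrow = TRUE))
  expect_error(normalize_counts(zero, "library_size"), "zero total")
})

test_that("log transform maps x to log2(x + 1) and rejects negatives", {
  expect_equal(log_transform(matrix(c(0, 1, 3))), matrix(c(0, 1, 2)))
  expect_error(log_transform(matrix(-1)), "negative")
})

test_that("pipeline applies filters in order and records provenance", {
  cm <- toy_counts_6x3()
  thr <- qc_thresholds(min_genes_per_good_cell = 0)
  out <- preprocess_pipeline(cm, thr, method = "none")
  expect_equal(dim(out), c(6L, 2L)) # cells unchanged, genes reduced to {1,3}
  expect_identical(out$gene_ids, c("g1", "g3"))
  expect_equal(as.matrix(out$values),
               log2(as.matrix(cm$values)[, c(1, 3)] + 1),
               ignore_attr = TRUE)
  expect_identical(out$provenance$normalization, "none")
  expect_length(out$provenance$good_cells, 6)
  # all genes filtered out -> explicit error, not a silent empty matrix
  weak <- count_matrix(matrix(1L, 4, 3))
  expect_error(preprocess_pipeline(weak, qc_thresholds(0)), "all genes")
  # all cells filtered out
  expect_error(preprocess_pipeline(cm, qc_thresholds(1000)), "all cells")
})

test_that("filter masks are idempotent and monotone in the thresholds", {
  set.seed(42)
  m <- matrix(rpois(50 * 20, 3), 50, 20)
  cm <- count_matrix(m)
  thr <- qc_thresholds(5, 2, 0.25)
  good <- identify_good_cells(cm, thr)
  expr_mask <- identify_expressed_genes(cm, good, thr)
  sub <- count_matrix(m[good, expr_mask, drop = FALSE],
                      cm$cell_ids[good], cm$gene_ids[expr_mask])
  good2 <- identify_good_cells(sub, thr)
  # provided the good-cell set is unchanged, re-filtering changes nothing
  if (all(good2)) {
    expr2 <- identify_expressed_genes(sub, good2, thr)
    expect_true(all(expr2))
  }
  # monotonicity across a threshold ladder
  for (mc in c(1, 3, 5)) {
    lo <- identify_expressed_genes(cm, good, qc_thresholds(5, mc, 0.1))
    hi <- identify_expressed_genes(cm, good, qc_thresholds(5, mc, 0.4))
    expect_true(all(which(hi) %in% which(lo)))
  }
  g_lo <- identify_good_cells(cm, qc_thresholds(2))
  g_hi <- identify_good_cells(cm, qc_thresholds(10))
  expect_true(all(which(g_hi) %in% which(g_lo)))
})

test_that("pipeline output is finite and rank order survives normalization", {
  set.seed(7)
  m <- matrix(rpois(30 * 15, 4), 30, 15)
  m[1, ] <- m[1, ] + 1 # no all-zero cells
  cm <- count_matrix(m)
  out <- preprocess_pipeline(cm, qc_thresholds(0, 1, 0.1))
  expect_true(all(is.finite(as.matrix(out$values))))
  expect_true(all(as.matrix(out$values) >= 0))
  norm <- normalize_counts(cm, "library_size")
  for (i in c(1, 15, 30))
    expect_identical(order(norm[i, ]), order(m[i, ]))
})
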