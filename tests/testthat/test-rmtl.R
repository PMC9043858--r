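test_that("task losses at zero weights hit their closed-form values", {
  set.seed(1)
  tk <- task_data(matrix(rnorm(12), 6, 2), c(1, -1, 1, -1, 1, -1))
  expect_equal(task_loss(rep(0, 2), 0, tk, "logistic"), log(2))
  expect_equal(task_loss(rep(0, 2), 0, tk, "squared_hinge"), 1.0)
  single <- suppressWarnings(task_data(matrix(c(1, 0), 1, 2), 1))
  expect_equal(task_loss(c(10, 0), 0, single, "logistic"), log1p(exp(-10)))
  expect_error(task_loss(rep(0, 3), 0, tk, "logistic"), "match")
})

test_that("objective assembles loss and penalty terms in both modes", {
  tasks <- random_tasks(5)
  T_ <- length(tasks)
  p <- ncol(tasks[[1]]$X)
  zero_model <- list(W0 = rep(0, p), V = matrix(0, T_, p),
                     intercepts = rep(0, T_),
                     config = rmtl_config(lambda1 = 3, lambda2 = 7))
  expect_equal(rmtl_objective(zero_model, tasks), T_ * log(2))
  # lambda = 0: objective equals the sum of task losses
  set.seed(9)
  W0 <- rnorm(p); V <- matrix(rnorm(T_ * p), T_, p); b <- rnorm(T_)
  m0 <- list(W0 = W0, V = V, intercepts = b,
             config = rmtl_config(lambda1 = 0, lambda2 = 0))
  expect_equal(rmtl_objective(m0, tasks),
               sum(vapply(seq_len(T_), function(t)
                 task_loss(W0 + V[t, ], b[t], tasks[[t]], "logistic"),
                 numeric(1))))
  # term-by-term oracle, both regularizer modes
  for (mode in c("shared_offset", "l21")) {
    cfg <- rmtl_config(regularizer = mode, lambda1 = 0.3, lambda2 = 0.7)
    m <- list(W0 = W0, V = V, intercepts = b, config = cfg)
    loss_sum <- sum(vapply(seq_len(T_), function(t)
      task_loss(W0 + V[t, ], b[t], tasks[[t]], "logistic"), numeric(1)))
    W <- sweep(V, 2, W0, `+`)
    pen <- if (mode == "shared_offset") 0.3 * sum(W0^2) + 0.7 * sum(V^2)
           else 0.3 * sum(sqrt(colSums(W^2))) + 0.7 * sum(W^2)
    expect_equal(rmtl_objective(m, tasks), loss_sum + pen)
  }
})

test_that("l21 prox is exact group soft-thresholding", {
  W <- matrix(rnorm(12), 3, 4)
  expect_equal(l21_prox(W, 0), W)
  expect_equal(l21_prox(matrix(c(3, 4), 2, 1), 5), matrix(c(0, 0), 2, 1))
  expect_equal(l21_prox(matrix(c(3, 4), 2, 1), 2.5), matrix(c(1.5, 2), 2, 1))
  expect_error(l21_prox(W, -1), "non-negative")
  # numerical-minimization oracle on random groups
  set.seed(11)
  for (i in 1:25) {
    g <- rnorm(sample(1:4, 1))
    tau <- runif(1, 0, 2)
    expect_equal(l21_prox(matrix(g, ncol = 1), tau)[, 1],
                 oracle_group_prox(g, tau), tolerance = 1e-6)
  }
})

test_that("fit matches a generic joint minimizer on small instances", {
  for (s in 1:5) {
    tasks <- random_tasks(s)
    cfg <- rmtl_config(lambda1 = 0.1, lambda2 = 0.1, max_iter = 20000,
                       tol = 1e-12, standardize = FALSE)
    fit <- rmtl_fit(tasks, cfg)
    target <- oracle_shared_offset_min(tasks, 0.1, 0.1)
    got <- tail(fit$objective_trace, 1)
    expect_lt(abs(got - target) / max(1, abs(target)), 1e-4)
  }
})

test_that("penalty limits push V or W0 to zero", {
  tasks <- random_tasks(3)
  f1 <- rmtl_fit(tasks, rmtl_config(lambda1 = 0.01, lambda2 = 1e8,
                                    max_iter = 5000, tol = 1e-12,
                                    standardize = FALSE))
  expect_lt(max(sqrt(rowSums(f1$V^2))), 1e-3)
  f2 <- rmtl_fit(tasks, rmtl_config(lambda1 = 1e8, lambda2 = 0.01,
                                    max_iter = 5000, tol = 1e-12,
                                    standardize = FALSE))
  expect_lt(sqrt(sum(f2$W0^2)), 1e-3)
})

test_that("a separable toy is fit to training accuracy 1 at lambda 0", {
  X <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2, byrow = TRUE)
  y <- c(-1, -1, 1, 1)
  tasks <- list(task_data(X, y, "sep"))
  fit <- rmtl_fit(tasks, rmtl_config(lambda1 = 0, lambda2 = 0,
                                     max_iter = 3000, standardize = FALSE))
  sc <- predict_scores(fit, X)
  expect_equal(unname(sign(sc[, 1])), y)
})

test_that("fits are deterministic and traces are non-increasing", {
  tasks <- random_tasks(17)
  cfg <- rmtl_config(lambda1 = 0.05, lambda2 = 0.05, seed = 99)
  f1 <- rmtl_fit(tasks, cfg)
  f2 <- rmtl_fit(tasks, cfg)
  expect_identical(f1$objective_trace, f2$objective_trace)
  expect_identical(f1$W0, f2$W0)
  expect_true(all(diff(f1$objective_trace) <= 1e-12))
  f3 <- rmtl_fit(tasks, rmtl_config(regularizer = "l21", lambda1 = 0.2,
                                    lambda2 = 0.05, standardize = FALSE))
  expect_true(all(diff(f3$objective_trace) <= 1e-12))
})

test_that("objective is convex along random segments in both modes", {
  tasks <- random_tasks(23)
  T_ <- length(tasks)
  p <- ncol(tasks[[1]]$X)
  set.seed(31)
  for (mode in c("shared_offset", "l21")) {
    cfg <- rmtl_config(regularizer = mode, lambda1 = 0.4, lambda2 = 0.2)
    for (r in 1:10) {
      m1 <- list(W0 = rnorm(p), V = matrix(rnorm(T_ * p), T_, p),
                 intercepts = rnorm(T_), config = cfg)
      m2 <- list(W0 = rnorm(p), V = matrix(rnorm(T_ * p), T_, p),
                 intercepts = rnorm(T_), config = cfg)
      mid <- list(W0 = (m1$W0 + m2$W0) / 2, V = (m1$V + m2$V) / 2,
                  intercepts = (m1$intercepts + m2$intercepts) / 2,
                  config = cfg)
      expect_lte(rmtl_objective(mid, tasks),
                 mean(c(rmtl_objective(m1, tasks),
                        rmtl_objective(m2, tasks))) + 1e-10)
    }
  }
})

test_that("predict_scores reduces to explicit dot products", {
  tasks <- random_tasks(7)
  fit <- rmtl_fit(tasks, rmtl_config(standardize = FALSE, max_iter = 50))
  # all-zero model scores equal the intercepts
  zero <- fit
  zero$W <- 0 * zero$W
  Xq <- matrix(rnorm(3 * ncol(tasks[[1]]$X)), 3)
  sc0 <- predict_scores(zero, Xq)
  expect_equal(unname(sc0),
               matrix(rep(fit$intercepts, each = 3), nrow = 3))
  # loop oracle
  sc <- predict_scores(fit, Xq)
  for (i in 1:3)
    for (t in seq_along(tasks))
      expect_equal(sc[i, t], sum(Xq[i, ] * fit$W[t, ]) + fit$intercepts[t],
                   ignore_attr = TRUE)
  expect_error(predict_scores(fit, Xq[, -1, drop = FALSE]),
               "expected .* got|feature count")
})

test_that("lambda selection returns single points unchanged and breaks ties
           toward stronger regularization", {
  set.seed(41)
  n <- 30; p <- 4
  tasks <- lapply(1:2, function(t) {
    X <- matrix(rnorm(n * p), n, p)
    w <- c(2, -2, 0, 0)
    y <- sign(X %*% w + rnorm(n) * 0.3); y[y == 0] <- 1
    task_data(X, drop(y), paste0("t", t))
  })
  cfg <- rmtl_config(max_iter = 200, seed = 5)
  one <- cv_select_lambdas(tasks, cfg, lambda1_grid = 0.1,
                           lambda2_grid = 0.2, k = 3)
  expect_equal(one$lambda1, 0.1)
  expect_equal(one$lambda2, 0.2)
  expect_equal(nrow(one$cv_table), 1L)
  # duplicated grid values collapse; choice is deterministic
  dup <- cv_select_lambdas(tasks, cfg, lambda1_grid = c(0.1, 0.1),
                          lambda2_grid = c(0.2, 0.2), k = 3)
  expect_equal(dup$lambda1, 0.1)
  # an absurd lambda2 is not selected when it degrades held-out accuracy
  sel <- cv_select_lambdas(tasks, cfg, lambda1_grid = 0.01,
                           lambda2_grid = c(0.01, 1e6), k = 3)
  best_small <- sel$cv_table$accuracy[sel$cv_table$lambda2 == 0.01]
  best_big <- sel$cv_table$accuracy[sel$cv_table$lambda2 == 1e6]
  if (best_small > best_big) expect_equal(sel$lambda2, 0.01)
  else expect_equal(sel$lambda2, 1e6) # tie or better: rule picks larger
})
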