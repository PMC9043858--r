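# shared fixtures and independent oracles, built in code at test time

# the 6-cell x 3-gene worked example for the expressed-gene filter
toy_counts_6x3 <- function() {
  m <- matrix(c(6, 0, 9,
                7, 0, 9,
                6, 1, 9,
                0, 2, 9,
                0, 3, 9,
                0, 5, 9), nrow = 6, byrow = TRUE)
  count_matrix(m, paste0("c", 1:6), paste0("g", 1:3))
}

# random small multi-task instance with both classes per task
random_tasks <- function(seed, T_max = 3, n_max = 30, p_max = 6) {
  set.seed(seed)
  T_ <- sample(1:T_max, 1)
  n <- sample(8:n_max, 1)
  p <- sample(2:p_max, 1)
  lapply(seq_len(T_), function(t) {
    X <- matrix(rnorm(n * p), n, p)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- -y[1]
    task_data(X, y, paste0("task", t))
  })
}

# independent joint minimizer of the shared-offset logistic objective
# over all parameters, via a generic quasi-Newton optimizer
oracle_shared_offset_min <- function(tasks, lambda1, lambda2) {
  T_ <- length(tasks)
  p <- ncol(tasks[[1]]$X)
  fn <- function(theta) {
    W0 <- theta[seq_len(p)]
    V <- matrix(theta[p + seq_len(T_ * p)], T_, byrow = TRUE)
    b <- theta[p + T_ * p + seq_len(T_)]
    s <- 0
    for (t in seq_len(T_)) {
      m <- drop(tasks[[t]]$X %*% (W0 + V[t, ])) + b[t]
      s <- s + mean(log1p(exp(pmin(700, -tasks[[t]]$y * m))))
    }
    s + lambda1 * sum(W0^2) + lambda2 * sum(V^2)
  }
  stats::optim(numeric(p + T_ * p + T_), fn, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-14))$value
}

# numerical minimizer of 0.5||z - g||^2 + tau ||z||_2: the optimum is a
# non-negative scaling alpha * g (any off-ray component only increases
# both terms), so minimize the 1-D section by golden search
oracle_group_prox <- function(g, tau) {
  ng2 <- sum(g^2)
  if (ng2 == 0) return(g * 0)
  h <- function(alpha) 0.5 * (alpha - 1)^2 * ng2 + tau * alpha * sqrt(ng2)
  alpha <- stats::optimize(h, c(0, 1), tol = 1e-12)$minimum
  if (h(0) <= h(alpha)) alpha <- 0
  alpha * g
}

# small well-separated two/three-class labeled dataset for fast unit tests
toy_labeled <- function(seed = 1, n_per = 40, p = 25, k = 2, sep = 3) {
  set.seed(seed)
  centers <- matrix(rnorm(k * p), k, p) * sep
  X <- do.call(rbind, lapply(seq_len(k), function(g)
    sweep(matrix(rnorm(n_per * p, sd = 1), n_per, p), 2, centers[g, ], `+`)))
  X <- pmax(X, 0) # log-expression is non-negative
  labels <- rep(paste0("type", seq_len(k)), each = n_per)
  labeled_dataset(expression_matrix(X), labels)
}

# preset-scale simulated dataset, preprocessed; memoised per option set
.sim_cache <- new.env(parent = emptyenv())
sim_labeled <- function(seed, preset = "data1", ...) {
  key <- paste(seed, preset, paste(deparse(list(...)), collapse = ""),
               sep = "|")
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  sim <- simulate_counts(sim_preset(preset, seed = seed, ...))
  expr <- preprocess_pipeline(sim$counts)
  d <- labeled_dataset(expr,
                       sim$labels[match(expr$cell_ids, sim$counts$cell_ids)])
  .sim_cache[[key]] <- d
  d
}
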