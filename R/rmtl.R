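#' Binary task data for the multi-task learner
#'
#' One one-vs-rest task: a design matrix and a label vector coded
#' +1/-1. Tasks in a task set must share the feature dimension (and,
#' for cell typing, the gene order).
#'
#' @param X numeric design matrix, samples x features, no NaN/Inf.
#' @param y numeric vector in `{+1, -1}`, length `nrow(X)`.
#' @param task_name character scalar.
#' @return Object of class `task_data`.
#' @export
task_data <- function(X, y, task_name = "task") {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X contains NaN/Inf", call. = FALSE)
  y <- as.numeric(y)
  if (length(y) != nrow(X))
    stop("length(y) != nrow(X)", call. = FALSE)
  if (!all(y %in% c(-1, 1)))
    stop("labels must be coded +1/-1", call. = FALSE)
  if (length(unique(y)) < 2L)
    warning(sprintf("task '%s' has a single class; fit is degenerate",
                    task_name), call. = FALSE)
  structure(list(X = X, y = y, task_name = as.character(task_name)),
            class = "task_data")
}

#' Configuration for the regularized multi-task learner
#'
#' @param loss `"logistic"` (default; smooth, probabilistic margins) or
#'   `"squared_hinge"` (SVM-flavoured, also differentiable).
#' @param regularizer `"shared_offset"` (default): every task weight
#'   vector is `W0 + V_t`, with `lambda1*||W0||^2` penalizing the shared
#'   part and `lambda2*sum_t ||V_t||^2` the task offsets. `"l21"`: the
#'   task weight matrix `W` (tasks x features) is penalized by
#'   `lambda1 * sum_j ||W[, j]||_2` (joint feature selection across
#'   tasks) plus `lambda2 * ||W||_F^2`.
#' @param lambda1,lambda2 non-negative regularization strengths.
#' @param max_iter maximum accelerated-gradient iterations.
#' @param tol relative objective-change stopping tolerance.
#' @param step_init initial step size (inverse Lipschitz guess) for the
#'   backtracking line search.
#' @param seed integer seed; consumed by cross-validation fold draws
#'   (the fit itself is deterministic from a zero start).
#' @param standardize center/scale features by training statistics
#'   before fitting; the scaler is stored in the model and applied at
#'   prediction time. Penalized linear models are scale-sensitive, so
#'   this defaults to `TRUE`.
#' @param fit_intercept estimate an unpenalized intercept per task.
#' @return Object of class `rmtl_config`.
#' @export
rmtl_config <- function(loss = c("logistic", "squared_hinge"),
                        regularizer = c("shared_offset", "l21"),
                        lambda1 = 0.01, lambda2 = 0.01,
                        max_iter = 1000L, tol = 1e-6,
                        step_init = 1.0, seed = 1L,
                        standardize = TRUE, fit_intercept = TRUE) {
  loss <- match.arg(loss)
  regularizer <- match.arg(regularizer)
  stopifnot(lambda1 >= 0, lambda2 >= 0, tol > 0, max_iter >= 1,
            step_init > 0)
  structure(list(loss = loss, regularizer = regularizer,
                 lambda1 = lambda1, lambda2 = lambda2,
                 max_iter = as.integer(max_iter), tol = tol,
                 step_init = step_init, seed = as.integer(seed),
                 standardize = isTRUE(standardize),
                 fit_intercept = isTRUE(fit_intercept)),
            class = "rmtl_config")
}

# stable log(1 + exp(z))
log1pexp <- function(z) ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))

#' Per-task empirical loss
#'
#' Mean loss of a linear model over one task's samples. Logistic:
#' `mean(log(1 + exp(-y * (Xw + b))))`; squared hinge:
#' `mean(pmax(0, 1 - y * (Xw + b))^2)`.
#'
#' @param w weight vector, length `ncol(task$X)`.
#' @param b intercept scalar.
#' @param task a [task_data()].
#' @param loss `"logistic"` or `"squared_hinge"`.
#' @return Non-negative scalar.
#' @export
task_loss <- function(w, b, task, loss = c("logistic", "squared_hinge")) {
  loss <- match.arg(loss)
  if (length(w) != ncol(task$X))
    stop(sprintf("weight length %d does not match %d features",
                 length(w), ncol(task$X)), call. = FALSE)
  m <- drop(task$X %*% w) + b
  if (loss == "logistic") {
    mean(log1pexp(-task$y * m))
  } else {
    mean(pmax(0, 1 - task$y * m)^2)
  }
}

# derivative of the per-sample loss wrt the margin m, as a vector
loss_grad_margin <- function(m, y, loss) {
  if (loss == "logistic") {
    -y / (1 + exp(y * m))
  } else {
    -2 * y * pmax(0, 1 - y * m)
  }
}

#' Proximal operator of the L2,1 norm over feature groups
#'
#' Applies group soft-thresholding to each column of `W` (the values of
#' one feature across tasks): a group `g` maps to
#' `g * max(0, 1 - tau / ||g||_2)` and to zero when `||g||_2 <= tau`.
#' This is the exact minimizer of `0.5 * ||Z - W||_F^2 + tau *
#' sum_j ||Z[, j]||_2`.
#'
#' @param W numeric matrix, tasks x features.
#' @param tau non-negative threshold.
#' @return Matrix of the same shape.
#' @export
l21_prox <- function(W, tau) {
  if (tau < 0) stop("tau must be non-negative", call. = FALSE)
  W <- as.matrix(W)
  if (tau == 0) return(W)
  nrm <- sqrt(colSums(W^2))
  shrink <- pmax(0, 1 - tau / pmax(nrm, .Machine$double.eps))
  shrink[nrm == 0] <- 0
  sweep(W, 2, shrink, `*`)
}

l21_norm <- function(W) sum(sqrt(colSums(as.matrix(W)^2)))

#' Regularized multi-task objective
#'
#' Evaluates the full penalized objective for a parameter set.
#' `shared_offset` mode: `sum_t task_loss(W0 + V_t, b_t) +
#' lambda1 * ||W0||^2 + lambda2 * sum_t ||V_t||^2`. `l21` mode:
#' `sum_t task_loss(W_t, b_t) + lambda1 * ||W||_{2,1} +
#' lambda2 * ||W||_F^2` with `W_t = W0 + V_t` the effective weights.
#'
#' @param model an `rmtl_model`, or any list with elements `W0`
#'   (feature-length vector), `V` (tasks x features matrix),
#'   `intercepts` (task-length vector) and `config` (an
#'   [rmtl_config()]).
#' @param tasks list of [task_data()]. If the model carries a scaler
#'   (fitted with `standardize = TRUE`), task design matrices are
#'   standardized with it before evaluation, so the value refers to the
#'   same coordinates the optimizer used.
#' @return Non-negative scalar.
#' @export
rmtl_objective <- function(model, tasks) {
  cfg <- model$config
  W0 <- model$W0
  V <- as.matrix(model$V)
  b <- model$intercepts
  if (!is.null(model$scaler))
    tasks <- lapply(tasks, scale_task, scaler = model$scaler)
  W <- sweep(V, 2, W0, `+`)
  data_term <- sum(vapply(seq_along(tasks), function(t)
    task_loss(W[t, ], b[t], tasks[[t]], cfg$loss), numeric(1)))
  if (cfg$regularizer == "shared_offset") {
    data_term + cfg$lambda1 * sum(W0^2) + cfg$lambda2 * sum(V^2)
  } else {
    data_term + cfg$lambda1 * l21_norm(W) + cfg$lambda2 * sum(W^2)
  }
}

# ---- internal: parameter packing -------------------------------------------

# theta layout: [W0 (p)] [V (T*p, row-major by task)] [b (T)] for
# shared_offset; [W (T*p)] [b (T)] for l21 (W0 held at zero).
pack_params <- function(W0, V, b) c(W0, as.vector(t(V)), b)

unpack_params <- function(theta, T_, p, mode) {
  if (mode == "shared_offset") {
    W0 <- theta[seq_len(p)]
    V <- matrix(theta[p + seq_len(T_ * p)], nrow = T_, byrow = TRUE)
    b <- theta[p + T_ * p + seq_len(T_)]
  } else {
    W0 <- numeric(p)
    V <- matrix(theta[seq_len(T_ * p)], nrow = T_, byrow = TRUE)
    b <- theta[T_ * p + seq_len(T_)]
  }
  list(W0 = W0, V = V, b = b)
}

# smooth part (the data loss only) and its gradient; the penalties are
# handled exactly in the proximal step, which keeps the line-search step
# governed by the loss curvature rather than by large lambda values
smooth_eval <- function(theta, tasks, cfg, T_, p, want_grad = TRUE) {
  pars <- unpack_params(theta, T_, p, cfg$regularizer)
  W <- sweep(pars$V, 2, pars$W0, `+`)
  val <- 0
  gW <- matrix(0, T_, p)
  gb <- numeric(T_)
  for (t in seq_len(T_)) {
    Xt <- tasks[[t]]$X
    yt <- tasks[[t]]$y
    nt <- length(yt)
    m <- drop(Xt %*% W[t, ]) + pars$b[t]
    if (cfg$loss == "logistic") {
      val <- val + sum(log1pexp(-yt * m)) / nt
    } else {
      val <- val + sum(pmax(0, 1 - yt * m)^2) / nt
    }
    if (want_grad) {
      d <- loss_grad_margin(m, yt, cfg$loss) / nt
      gW[t, ] <- drop(crossprod(Xt, d))
      gb[t] <- if (cfg$fit_intercept) sum(d) else 0
    }
  }
  if (!want_grad) return(list(value = val))
  if (cfg$regularizer == "shared_offset") {
    list(value = val, grad = pack_params(colSums(gW), gW, gb))
  } else {
    list(value = val, grad = c(as.vector(t(gW)), gb))
  }
}

# the penalty terms (all treated through their proximal maps)
nonsmooth_eval <- function(theta, cfg, T_, p) {
  pars <- unpack_params(theta, T_, p, cfg$regularizer)
  if (cfg$regularizer == "shared_offset") {
    cfg$lambda1 * sum(pars$W0^2) + cfg$lambda2 * sum(pars$V^2)
  } else {
    W <- pars$V
    cfg$lambda1 * l21_norm(W) + cfg$lambda2 * sum(W^2)
  }
}

# exact prox of step * penalty: ridge terms shrink multiplicatively
# (argmin_z ||z - x||^2/2 + s*l*||z||^2 = x / (1 + 2 s l)); the combined
# l21 + ridge prox is group soft-thresholding of the ridge-shrunk point
prox_step <- function(theta, step, cfg, T_, p) {
  if (cfg$regularizer == "shared_offset") {
    i_w0 <- seq_len(p)
    i_v <- p + seq_len(T_ * p)
    theta[i_w0] <- theta[i_w0] / (1 + 2 * step * cfg$lambda1)
    theta[i_v] <- theta[i_v] / (1 + 2 * step * cfg$lambda2)
    theta
  } else {
    shrink <- 1 + 2 * step * cfg$lambda2
    W <- matrix(theta[seq_len(T_ * p)], nrow = T_, byrow = TRUE) / shrink
    W <- l21_prox(W, step * cfg$lambda1 / shrink)
    c(as.vector(t(W)), theta[T_ * p + seq_len(T_)])
  }
}

# ---- internal: feature scaler ----------------------------------------------

fit_scaler <- function(tasks) {
  pool <- do.call(rbind, lapply(tasks, `[[`, "X"))
  center <- colMeans(pool)
  scl <- apply(pool, 2, stats::sd)
  scl[!is.finite(scl) | scl < .Machine$double.eps] <- 1
  list(center = center, scale = scl)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$center, `-`), 2, scaler$scale, `/`)
}

scale_task <- function(task, scaler) {
  task$X <- apply_scaler(task$X, scaler)
  task
}

# ---- fitting ----------------------------------------------------------------

#' Fit the regularized multi-task model
#'
#' Jointly estimates the shared weight vector `W0`, the task-specific
#' offsets `V` and the intercepts by monotone accelerated (proximal)
#' gradient descent with backtracking line search. In `shared_offset`
#' mode the objective is smooth and the proximal step is the identity;
#' in `l21` mode the group soft-threshold [l21_prox()] is applied each
#' step. Whenever the accelerated step would increase the objective the
#' momentum is restarted and a plain descent step is taken instead, so
#' the recorded objective trace is non-increasing. Each task's loss is
#' averaged over its own samples, equalizing task influence under
#' unequal class sizes. Initialization is at zero, making the fit
#' deterministic given its inputs.
#'
#' @param tasks non-empty list of [task_data()] sharing `ncol(X)`.
#' @param config an [rmtl_config()].
#' @return Object of class `rmtl_model` with elements `W0`, `V`,
#'   `intercepts`, `W` (derived, row `t` is `W0 + V_t`), `scaler`,
#'   `config`, `objective_trace`, `n_iter`, `converged`.
#' @export
rmtl_fit <- function(tasks, config = rmtl_config()) {
  stopifnot(length(tasks) >= 1L)
  tasks <- lapply(tasks, function(t)
    if (inherits(t, "task_data")) t else do.call(task_data, t))
  p <- ncol(tasks[[1]]$X)
  if (!all(vapply(tasks, function(t) ncol(t$X) == p, logical(1))))
    stop("all tasks must share the feature dimension", call. = FALSE)
  T_ <- length(tasks)

  scaler <- NULL
  if (config$standardize) {
    scaler <- fit_scaler(tasks)
    tasks <- lapply(tasks, scale_task, scaler = scaler)
  }

  n_par <- if (config$regularizer == "shared_offset") p + T_ * p + T_
           else T_ * p + T_
  x <- numeric(n_par)
  fx <- smooth_eval(x, tasks, config, T_, p, want_grad = FALSE)$value
  obj <- fx + nonsmooth_eval(x, config, T_, p)
  trace <- obj
  yv <- x
  tk <- 1
  L <- 1 / config$step_init
  converged <- FALSE
  iter <- 0L

  backtrack <- function(from, fv, gv, L) {
    repeat {
      step <- 1 / L
      cand <- prox_step(from - step * gv, step, config, T_, p)
      d <- cand - from
      fc <- smooth_eval(cand, tasks, config, T_, p, want_grad = FALSE)$value
      if (fc <= fv + sum(gv * d) + (L / 2) * sum(d^2) + 1e-12)
        return(list(x = cand, f = fc, L = L))
      L <- L * 2
      if (L > 1e18) return(list(x = from, f = fv, L = L))
    }
  }

  while (iter < config$max_iter) {
    iter <- iter + 1L
    sy <- smooth_eval(yv, tasks, config, T_, p)
    bt <- backtrack(yv, sy$value, sy$grad, L)
    L <- bt$L
    xn <- bt$x
    objn <- bt$f + nonsmooth_eval(xn, config, T_, p)
    if (objn > obj) {
      # accelerated step overshot: restart momentum, plain descent from x
      sx <- smooth_eval(x, tasks, config, T_, p)
      bt <- backtrack(x, sx$value, sx$grad, L)
      L <- bt$L
      xn <- bt$x
      objn <- bt$f + nonsmooth_eval(xn, config, T_, p)
      tk <- 1
      if (objn > obj) { # numerically stuck; keep current iterate and stop
        trace <- c(trace, obj)
        converged <- TRUE
        break
      }
    }
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    yv <- xn + ((tk - 1) / tn) * (xn - x)
    rel <- abs(obj - objn) / max(1, abs(obj))
    x <- xn
    obj <- objn
    tk <- tn
    trace <- c(trace, obj)
    if (rel < config$tol) { converged <- TRUE; break }
    L <- max(L / 2, 1e-12) # allow the step to grow back between iterations
  }

  pars <- unpack_params(x, T_, p, config$regularizer)
  W <- sweep(pars$V, 2, pars$W0, `+`)
  rownames(W) <- rownames(pars$V) <- vapply(tasks, `[[`, "", "task_name")
  structure(list(W0 = pars$W0, V = pars$V, intercepts = pars$b, W = W,
                 scaler = scaler, config = config,
                 objective_trace = trace, n_iter = iter,
                 converged = converged,
                 task_names = vapply(tasks, `[[`, "", "task_name"),
                 n_features = p),
            class = "rmtl_model")
}

#' @export
print.rmtl_model <- function(x, ...) {
  cat(sprintf(
    "rmtl_model: %d tasks, %d features (%s loss, %s regularizer)\n",
    nrow(x$V), x$n_features, x$config$loss, x$config$regularizer))
  cat(sprintf("  lambda1 = %g, lambda2 = %g; %d iterations%s; objective %.6g\n",
              x$config$lambda1, x$config$lambda2, x$n_iter,
              if (x$converged) " (converged)" else "",
              utils::tail(x$objective_trace, 1)))
  invisible(x)
}

#' Per-task decision scores
#'
#' Computes `score[i, t] = X[i, ] . (W0 + V_t) + intercept_t` after
#' applying the model's stored feature scaler (when fitted with
#' standardization).
#'
#' @param model an `rmtl_model`.
#' @param X numeric matrix with `model$n_features` columns (pre-scaling
#'   coordinates, i.e. the same space the training data was given in).
#' @return Numeric matrix, rows = samples, columns = tasks.
#' @export
predict_scores <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_features)
    stop(sprintf("feature count mismatch: expected %d, got %d",
                 model$n_features, ncol(X)), call. = FALSE)
  if (!is.null(model$scaler)) X <- apply_scaler(X, model$scaler)
  sc <- X %*% t(model$W)
  sc <- sweep(sc, 2, model$intercepts, `+`)
  colnames(sc) <- model$task_names
  sc
}

# ---- cross-validated lambda selection ---------------------------------------

#' Select regularization strengths by cross-validation
#'
#' Grid search over `(lambda1, lambda2)` pairs scored by mean held-out
#' sign accuracy across tasks and stratified folds. Ties are broken
#' toward larger `lambda1`, then larger `lambda2` (the more regularized
#' model).
#'
#' @param tasks list of [task_data()].
#' @param config an [rmtl_config()]; its `seed` fixes the fold draw.
#' @param lambda1_grid,lambda2_grid non-empty numeric grids; defaults
#'   span `10^(-3..2)`.
#' @param k number of folds (>= 2); every task needs at least `k`
#'   samples.
#' @return List with `lambda1`, `lambda2`, and `cv_table` (a data frame
#'   of mean held-out accuracy per grid pair).
#' @export
cv_select_lambdas <- function(tasks, config = rmtl_config(),
                              lambda1_grid = 10^seq(-3, 2),
                              lambda2_grid = 10^seq(-3, 2),
                              k = 5L) {
  stopifnot(length(lambda1_grid) >= 1, length(lambda2_grid) >= 1, k >= 2)
  if (any(vapply(tasks, function(t) length(t$y), integer(1)) < k))
    stop("every task needs at least k samples", call. = FALSE)
  folds <- lapply(seq_along(tasks), function(t)
    stratified_fold_ids(tasks[[t]]$y, k,
                        seed = derive_seed(config$seed, paste0("cvfold", t))))
  grid <- expand.grid(lambda1 = sort(unique(lambda1_grid)),
                      lambda2 = sort(unique(lambda2_grid)))
  grid$accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    cfg$lambda1 <- grid$lambda1[g]
    cfg$lambda2 <- grid$lambda2[g]
    accs <- numeric(0)
    for (f in seq_len(k)) {
      tr <- lapply(seq_along(tasks), function(t) {
        idx <- folds[[t]] != f
        task_data(tasks[[t]]$X[idx, , drop = FALSE], tasks[[t]]$y[idx],
                  tasks[[t]]$task_name)
      })
      fit <- rmtl_fit(tr, cfg)
      for (t in seq_along(tasks)) {
        idx <- folds[[t]] == f
        if (!any(idx)) next
        sc <- predict_scores(fit, tasks[[t]]$X[idx, , drop = FALSE])[, t]
        pred <- ifelse(sc >= 0, 1, -1)
        accs <- c(accs, mean(pred == tasks[[t]]$y[idx]))
      }
    }
    grid$accuracy[g] <- mean(accs)
  }
  # max accuracy; ties toward larger lambda1 then larger lambda2
  ord <- order(-grid$accuracy, -grid$lambda1, -grid$lambda2)
  best <- grid[ord[1], ]
  list(lambda1 = best$lambda1, lambda2 = best$lambda2, cv_table = grid)
}

# stratified fold assignment for +/-1 (or factor) labels; redraws until
# every fold's training complement holds both classes, when feasible
stratified_fold_ids <- function(y, k, seed, max_redraw = 20L) {
  n <- length(y)
  draw <- function() {
    ids <- integer(n)
    for (cls in unique(y)) {
      idx <- which(y == cls)
      ids[idx] <- (sample(seq_along(idx)) - 1L) %% k + 1L
    }
    ids
  }
  res <- with_seed(seed, {
    found <- NULL
    for (r in seq_len(max_redraw)) {
      ids <- draw()
      ok <- all(vapply(seq_len(k), function(f)
        length(unique(y[ids != f])) == length(unique(y)), logical(1)))
      if (ok) { found <- ids; break }
    }
    found
  })
  if (is.null(res))
    stop("could not build stratified folds with both classes in every ",
         "training split", call. = FALSE)
  res
}
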