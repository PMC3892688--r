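#' Solver settings for the proximal-gradient and dual solvers
#'
#' @param max_iter Maximum number of iterations (proximal-gradient steps,
#'   or epochs for the hinge-loss dual solver).
#' @param tol Relative objective-change tolerance declaring convergence.
#' @param step_init Optional initial step size; by default `1/L` with `L`
#'   the Lipschitz constant of the smooth loss gradient, estimated by power
#'   iteration.
#' @param verbose Print objective values while solving.
#' @return A list of class `solver_control`.
#' @export
solver_control <- function(max_iter = 1000L, tol = 1e-6, step_init = NULL,
                           verbose = FALSE) {
  stopifnot(max_iter >= 1L, tol > 0)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 step_init = step_init, verbose = isTRUE(verbose)),
            class = "solver_control")
}

LOSSES <- c("least_square", "logistic", "hinge")
REGULARIZERS <- c("l2", "l1", "group", "sparse_group")

#' Loss value and exact gradient of a smooth classification loss
#'
#' Losses are averaged over samples; labels are in `{-1, +1}`.
#' `least_square` is `mean((Xw + b - y)^2)`; `logistic` is
#' `mean(log(1 + exp(-y (Xw + b))))`. The hinge loss is handled by its own
#' dual solver ([fit_binary()]) and has no gradient here.
#'
#' @param loss `"least_square"` or `"logistic"`.
#' @param w Weight vector (length `d`).
#' @param b Intercept.
#' @param X `n x d` feature matrix.
#' @param y Length-`n` label vector in `{-1, +1}`.
#' @param sample_weights Optional nonnegative weights (renormalized to mean
#'   1); default equal.
#' @return List with `value` (scalar) and `grad` (length `d + 1`: weight
#'   gradient then intercept gradient).
#' @export
loss_value_grad <- function(loss, w, b, X, y, sample_weights = NULL) {
  loss <- match.arg(loss, c("least_square", "logistic"))
  n <- nrow(X)
  sw <- if (is.null(sample_weights)) rep(1, n) else sample_weights * n / sum(sample_weights)
  eta <- drop(X %*% w) + b
  if (loss == "least_square") {
    r <- eta - y
    value <- mean(sw * r^2)
    g <- (2 / n) * (sw * r)
  } else {
    z <- y * eta
    value <- mean(sw * log1p_exp(-z))
    g <- (1 / n) * (sw * (-y) / (1 + exp(z)))
  }
  list(value = value, grad = c(drop(crossprod(X, g)), sum(g)))
}

# numerically stable log(1 + exp(u))
log1p_exp <- function(u) {
  out <- u
  pos <- u > 0
  out[pos] <- u[pos] + log1p(exp(-u[pos]))
  out[!pos] <- log1p(exp(u[!pos]))
  out
}

#' Soft-thresholding: proximal operator of the l1 norm
#'
#' Returns the minimizer of `0.5 * ||u - v||^2 + t * ||u||_1`, i.e.
#' componentwise `sign(v) * max(|v| - t, 0)`.
#'
#' @param v Numeric vector.
#' @param t Threshold, `t >= 0`.
#' @return Vector of the same length as `v`.
#' @export
prox_l1 <- function(v, t) {
  if (t < 0) stop("threshold t must be nonnegative")
  sign(v) * pmax(abs(v) - t, 0)
}

#' Block soft-thresholding: proximal operator of the group Lasso penalty
#'
#' Returns the minimizer of `0.5 * ||u - v||^2 + t * sum_G ||u_G||_2` over
#' the given disjoint groups: each block is scaled by
#' `max(1 - t / ||v_G||_2, 0)`, vanishing entirely when its norm is within
#' the threshold.
#'
#' @param v Numeric vector.
#' @param t Threshold, `t >= 0`.
#' @param groups List of disjoint index vectors partitioning
#'   `seq_along(v)`.
#' @return Vector of the same length as `v`.
#' @export
prox_group <- function(v, t, groups) {
  if (t < 0) stop("threshold t must be nonnegative")
  check_partition(groups, length(v))
  out <- v
  for (g in groups) {
    nrm <- sqrt(sum(v[g]^2))
    out[g] <- if (nrm <= t) 0 else v[g] * (1 - t / nrm)
  }
  out
}

#' Proximal operator of the sparse group Lasso penalty
#'
#' The penalty `t1 * ||u||_1 + t2 * sum_G ||u_G||_2` induces sparsity both
#' between groups (whole image regions dropped) and within groups
#' (individual filters dropped inside a kept region). Its exact proximal
#' operator is the composition of the two: soft-threshold first, block
#' soft-threshold second.
#'
#' @param v Numeric vector.
#' @param t1 l1 threshold, `>= 0`.
#' @param t2 Group threshold, `>= 0`.
#' @param groups Disjoint partition of `seq_along(v)`.
#' @return Vector of the same length as `v`.
#' @export
prox_sparse_group <- function(v, t1, t2, groups) {
  if (t1 < 0 || t2 < 0) stop("thresholds must be nonnegative")
  prox_group(prox_l1(v, t1), t2, groups)
}

check_partition <- function(groups, d) {
  idx <- unlist(groups, use.names = FALSE)
  if (length(idx) != d || anyDuplicated(idx) || !setequal(idx, seq_len(d))) {
    stop("`groups` must be a disjoint partition of all feature indices")
  }
  invisible(TRUE)
}

# penalty value for a weight vector
penalty_value <- function(w, regularizer, lambda1, lambda2, gid = NULL) {
  switch(regularizer,
    l2 = lambda1 * sum(w^2),
    l1 = lambda1 * sum(abs(w)),
    group = lambda2 * sum(sqrt(rowsum(w^2, gid))),
    sparse_group = lambda1 * sum(abs(w)) +
      lambda2 * sum(sqrt(rowsum(w^2, gid))),
    stop("unknown regularizer")
  )
}

#' Smallest regularization strength that zeroes the solution
#'
#' For the Lasso (and the group Lasso at group level), the all-zero weight
#' vector solves the regularized problem exactly when the penalty strength
#' reaches the largest (group) norm of the loss gradient at `w = 0` with
#' the intercept at its unregularized optimum. Used to set default
#' penalties on a problem-relative scale.
#'
#' @param X `n x d` feature matrix.
#' @param y Labels in `{-1, +1}`.
#' @param loss `"least_square"` or `"logistic"`.
#' @param regularizer `"l1"` (default) or `"group"`.
#' @param groups Group partition, required for `"group"`.
#' @param sample_weights Optional sample weights.
#' @return The critical penalty strength (a nonnegative scalar).
#' @export
lambda_max <- function(X, y, loss = "logistic", regularizer = "l1",
                       groups = NULL, sample_weights = NULL) {
  loss <- match.arg(loss, c("least_square", "logistic"))
  regularizer <- match.arg(regularizer, c("l1", "group"))
  b0 <- optimal_intercept(loss, y, sample_weights)
  g <- loss_value_grad(loss, rep(0, ncol(X)), b0, X, y, sample_weights)$grad
  gw <- g[seq_len(ncol(X))]
  if (regularizer == "l1") {
    max(abs(gw))
  } else {
    gid <- group_ids(groups, ncol(X))
    max(sqrt(rowsum(gw^2, gid)))
  }
}

optimal_intercept <- function(loss, y, sample_weights = NULL) {
  sw <- if (is.null(sample_weights)) rep(1, length(y)) else sample_weights
  if (loss == "least_square") {
    sum(sw * y) / sum(sw)
  } else {
    p <- sum(sw * (y > 0)) / sum(sw)
    p <- min(max(p, 1e-12), 1 - 1e-12)
    log(p / (1 - p))
  }
}

group_ids <- function(groups, d) {
  check_partition(groups, d)
  gid <- integer(d)
  for (i in seq_along(groups)) gid[groups[[i]]] <- i
  gid
}

# Lipschitz constant of the smooth loss gradient over the augmented design
# [X 1], via power iteration on X^T X (a few matvecs suffice at the
# accuracy needed for a step size).
lipschitz_constant <- function(X, loss, sample_weights = NULL, iters = 30L) {
  n <- nrow(X)
  sw <- if (is.null(sample_weights)) rep(1, n) else sample_weights * n / sum(sample_weights)
  v <- rep(1, ncol(X) + 1L)
  v <- v / sqrt(sum(v^2))
  s2 <- 0
  for (i in seq_len(iters)) {
    u <- drop(X %*% v[-length(v)]) + v[length(v)]
    u <- sw * u
    v_new <- c(drop(crossprod(X, u)), sum(u))
    s2 <- sqrt(sum(v_new^2))
    if (s2 == 0) break
    v <- v_new / s2
  }
  if (loss == "least_square") 2 * s2 / n else s2 / (4 * n)
}

# Batched FISTA with backtracking for smooth-loss problems sharing a design
# matrix. Y is n x K in {-1,+1}; lambda1/lambda2 recycle to length K.
# Solves, for each column k,
#   min_{w,b} loss_k(w, b) + penalty(w; lambda1[k], lambda2[k])
# with the intercept unpenalized. Columns share the global step size (the
# loss Lipschitz constant does not depend on the labels), so acceleration,
# backtracking and convergence are monitored on the summed objective.
fista_solve <- function(X, Y, loss, regularizer, lambda1, lambda2,
                        groups = NULL, control = solver_control(),
                        sample_weights = NULL) {
  loss <- match.arg(loss, c("least_square", "logistic"))
  regularizer <- match.arg(regularizer, REGULARIZERS)
  Y <- as.matrix(Y)
  n <- nrow(X); d <- ncol(X); K <- ncol(Y)
  lambda1 <- rep_len(lambda1, K)
  lambda2 <- rep_len(lambda2, K)
  gid <- NULL
  if (regularizer %in% c("group", "sparse_group")) {
    if (is.null(groups)) stop("group regularizers require `groups`")
    gid <- group_ids(groups, d)
  }
  sw <- if (is.null(sample_weights)) NULL else sample_weights * n / sum(sample_weights)
  swv <- if (is.null(sw)) rep(1, n) else sw

  # value-only pass (one matrix product): used for backtracking and the
  # convergence check, where the gradient at the candidate is not needed
  smooth_vals <- function(W, B) {
    Eta <- sweep(X %*% W, 2L, B, `+`)
    if (loss == "least_square") {
      R <- Eta - Y
      colMeans(swv * R * R)
    } else {
      colMeans(swv * log1p_exp(-(Y * Eta)))
    }
  }

  smooth_val_grad <- function(W, B) {
    Eta <- X %*% W
    Eta <- sweep(Eta, 2L, B, `+`)
    if (loss == "least_square") {
      R <- Eta - Y
      vals <- colMeans(swv * R * R)
      G <- (2 / n) * (swv * R)
    } else {
      Z <- Y * Eta
      vals <- colMeans(swv * log1p_exp(-Z))
      G <- (1 / n) * (swv * (-Y) / (1 + exp(Z)))
    }
    list(vals = vals, GW = crossprod(X, G), GB = colSums(G))
  }

  prox_step <- function(V, t) {
    # V: d x K pre-prox point; t: step size
    switch(regularizer,
      l2 = V / (1 + 2 * t * matrix(lambda1, d, K, byrow = TRUE)),
      l1 = {
        Th <- matrix(t * lambda1, d, K, byrow = TRUE)
        sign(V) * pmax(abs(V) - Th, 0)
      },
      group = group_shrink(V, t * lambda2, gid),
      sparse_group = {
        Th <- matrix(t * lambda1, d, K, byrow = TRUE)
        group_shrink(sign(V) * pmax(abs(V) - Th, 0), t * lambda2, gid)
      }
    )
  }

  pen_vals <- function(W) {
    vapply(seq_len(K), function(k) {
      penalty_value(W[, k], regularizer, lambda1[k], lambda2[k], gid)
    }, numeric(1))
  }

  L <- lipschitz_constant(X, loss, sample_weights)
  step <- if (is.null(control$step_init)) 1 / max(L, .Machine$double.eps) else control$step_init

  W <- matrix(0, d, K); B <- rep(0, K)
  Wz <- W; Bz <- B
  tk <- 1
  obj <- sum(smooth_vals(W, B)) + sum(pen_vals(W))
  obj_trace <- obj
  converged <- FALSE
  for (it in seq_len(control$max_iter)) {
    sgz <- smooth_val_grad(Wz, Bz)
    repeat {
      W_new <- prox_step(Wz - step * sgz$GW, step)
      B_new <- Bz - step * sgz$GB
      vals_new <- smooth_vals(W_new, B_new)
      dW <- W_new - Wz; dB <- B_new - Bz
      quad <- sum(sgz$vals) + sum(dW * sgz$GW) + sum(dB * sgz$GB) +
        (sum(dW^2) + sum(dB^2)) / (2 * step)
      if (sum(vals_new) <= quad + 1e-12 * abs(quad)) break
      step <- step / 2
      if (step < 1e-16) break
    }
    obj_new <- sum(vals_new) + sum(pen_vals(W_new))
    if (obj_new <= obj) {
      # accepted: momentum continues from the new iterate
      tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
      mom <- (tk - 1) / tk_new
      Wz <- W_new + mom * (W_new - W)
      Bz <- B_new + mom * (B_new - B)
      W <- W_new; B <- B_new; tk <- tk_new
      rel <- abs(obj - obj_new) / max(abs(obj), 1e-12)
      obj <- obj_new
    } else {
      # monotone safeguard: reject the overshoot, restart momentum at the
      # current iterate (the next step is plain ISTA and must descend)
      Wz <- W; Bz <- B; tk <- 1
      rel <- Inf
    }
    if (control$verbose && it %% 50L == 0L) {
      message(sprintf("  iter %d: objective %.8g (rel change %.3g)", it,
                      obj, rel))
    }
    obj_trace <- c(obj_trace, obj)
    if (rel < control$tol && it > 1L) { converged <- TRUE; break }
  }
  list(W = W, b = B, objective = smooth_vals(W, B) + pen_vals(W),
       converged = converged, n_iter = it, obj_trace = obj_trace)
}

# block soft-threshold of each column of V with per-column thresholds t
group_shrink <- function(V, t, gid) {
  norms <- sqrt(rowsum(V * V, gid)) # S x K
  scale <- pmax(1 - sweep(1 / pmax(norms, 1e-300), 2L, t, `*`), 0)
  V * scale[gid, , drop = FALSE]
}

#' Fit a binary regularized linear classifier
#'
#' Minimizes `loss(w, b) + penalty(w)` for labels in `{-1, +1}`; the
#' intercept is never penalized. The seven supported configurations are the
#' hinge loss with ridge (`l2`) penalty -- a linear SVM, solved by dual
#' coordinate descent -- and the least-square or logistic loss with `l2`,
#' `l1` (Lasso), `group` (group Lasso) or `sparse_group` penalty, solved by
#' accelerated proximal gradient (FISTA) with backtracking line search.
#'
#' Penalty bookkeeping: `lambda1` is the l1 strength (and, for `l2`, the
#' ridge strength); `lambda2` is the group strength. The pure group Lasso
#' uses `lambda2` only.
#'
#' For the SVM the intercept is carried as an augmented constant feature
#' and therefore shares the ridge penalty (the standard linear-SVM
#' formulation); its objective is `mean(hinge) + lambda1 * (||w||^2 + b^2)`.
#'
#' @param X `n x d` feature matrix.
#' @param y Length-`n` labels in `{-1, +1}` (both classes must occur).
#' @param loss `"least_square"`, `"logistic"` or `"hinge"`.
#' @param regularizer `"l2"`, `"l1"`, `"group"` or `"sparse_group"`
#'   (`"hinge"` supports only `"l2"`).
#' @param lambda1,lambda2 Penalty strengths (see above), `>= 0`.
#' @param groups Feature partition for group penalties.
#' @param control A [solver_control()].
#' @param sample_weights Optional nonnegative per-sample weights.
#' @return A `linear_model`: weights, intercept, provenance fields, and a
#'   `converged` flag (non-convergence at `max_iter` is flagged, not an
#'   error).
#' @export
fit_binary <- function(X, y, loss = "logistic", regularizer = "l1",
                       lambda1 = 0, lambda2 = 0, groups = NULL,
                       control = solver_control(), sample_weights = NULL) {
  loss <- match.arg(loss, LOSSES)
  regularizer <- match.arg(regularizer, REGULARIZERS)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be in {-1, +1}")
  if (length(unique(y)) < 2L) stop("binary training set must contain both classes")
  if (lambda1 < 0 || lambda2 < 0) stop("penalty strengths must be nonnegative")
  if (loss == "hinge") {
    if (regularizer != "l2") {
      stop("the hinge loss is only available with the l2 (ridge) penalty")
    }
    if (lambda1 <= 0) stop("hinge + l2 requires lambda1 > 0")
    Cvec <- {
      sw <- if (is.null(sample_weights)) rep(1, nrow(X)) else
        sample_weights * nrow(X) / sum(sample_weights)
      sw / (2 * lambda1 * nrow(X))
    }
    fit <- svm_dual_cd(X, y, Cvec, max_epochs = control$max_iter,
                       eps = control$tol)
    model <- list(weights = fit$w, intercept = fit$b,
                  converged = fit$converged, n_iter = fit$epochs,
                  solver = "dual_coordinate_descent")
  } else {
    fit <- fista_solve(X, matrix(y, ncol = 1), loss, regularizer,
                       lambda1, lambda2, groups, control, sample_weights)
    model <- list(weights = drop(fit$W), intercept = fit$b,
                  converged = fit$converged, n_iter = fit$n_iter,
                  obj_trace = fit$obj_trace, solver = "fista")
  }
  if (!model$converged) {
    warning(sprintf("solver did not reach tolerance within %d iterations",
                    control$max_iter))
  }
  structure(c(model, list(loss = loss, regularizer = regularizer,
                          lambda1 = lambda1, lambda2 = lambda2,
                          groups = groups)),
            class = "linear_model")
}

#' @export
print.linear_model <- function(x, ...) {
  cat(sprintf("<linear_model %s + %s: %d features, %d nonzero, lambda1=%.3g lambda2=%.3g%s>\n",
              x$loss, x$regularizer, length(x$weights),
              sum(x$weights != 0), x$lambda1, x$lambda2,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @param object A `linear_model`.
#' @param newdata Matrix of feature rows.
#' @param type `"decision"` for real-valued scores `Xw + b`, `"class"` for
#'   labels in `{-1, +1}` (`sign`, with 0 mapped to +1).
#' @param ... Unused.
#' @rdname fit_binary
#' @export
predict.linear_model <- function(object, newdata, type = c("decision", "class"),
                                 ...) {
  type <- match.arg(type)
  s <- drop(as.matrix(newdata) %*% object$weights) + object$intercept
  if (type == "decision") s else ifelse(s >= 0, 1, -1)
}

#' Fit a one-vs-rest multiclass linear classifier
#'
#' Trains one binary model per class (that class = +1, all others = -1)
#' with a shared loss/penalty configuration. Penalty strengths default to
#' `lambda_scale` times each binary problem's [lambda_max()] (group-level
#' for the group Lasso; for the sparse group Lasso the two strengths are
#' set equal). Prediction takes the class with the largest decision value,
#' breaking ties toward the smallest class label.
#'
#' @param X `n x d` feature matrix.
#' @param y Length-`n` integer class labels (>= 2 distinct values).
#' @param loss,regularizer,groups,control,sample_weights As [fit_binary()].
#' @param lambda1,lambda2 Explicit penalty strengths; when `NULL` they are
#'   set per binary problem from `lambda_scale`.
#' @param lambda_scale Fraction of `lambda_max` used for automatic penalty
#'   strengths (default 0.01).
#' @param class_weights `"none"` (default) or `"balanced"`
#'   (inverse-frequency sample weights for each binary problem).
#' @return An `ovr_model` with the ordered `classes`, the `d x K` weight
#'   matrix `W`, intercepts `b`, and per-class metadata.
#' @export
fit_one_vs_rest <- function(X, y, loss = "logistic", regularizer = "l1",
                            lambda1 = NULL, lambda2 = NULL, groups = NULL,
                            lambda_scale = 0.01,
                            control = solver_control(),
                            class_weights = c("none", "balanced"),
                            sample_weights = NULL) {
  loss <- match.arg(loss, LOSSES)
  regularizer <- match.arg(regularizer, REGULARIZERS)
  class_weights <- match.arg(class_weights)
  X <- as.matrix(X)
  classes <- sort(unique(as.integer(y)))
  if (length(classes) < 2L) stop("need at least 2 classes")
  K <- length(classes)
  small <- classes[tabulate(match(y, classes)) < 2L]
  if (length(small)) {
    warning("classes with fewer than 2 samples: ",
            paste(small, collapse = ", "))
  }
  Y <- vapply(classes, function(cl) ifelse(y == cl, 1, -1), numeric(length(y)))
  per_class_sw <- function(yk) {
    sw <- if (is.null(sample_weights)) rep(1, length(yk)) else sample_weights
    if (class_weights == "balanced") {
      np <- sum(yk > 0); nn <- sum(yk < 0)
      sw <- sw * ifelse(yk > 0, length(yk) / (2 * np), length(yk) / (2 * nn))
    }
    sw
  }
  auto_lambda <- function(yk, sw) {
    base_loss <- if (loss == "hinge") "logistic" else loss
    if (regularizer == "group") {
      l2 <- lambda_scale * lambda_max(X, yk, base_loss, "group", groups, sw)
      c(0, l2)
    } else if (regularizer == "sparse_group") {
      l1 <- lambda_scale * lambda_max(X, yk, base_loss, "l1", NULL, sw)
      c(l1, l1)
    } else {
      c(lambda_scale * lambda_max(X, yk, base_loss, "l1", NULL, sw), 0)
    }
  }
  l1v <- numeric(K); l2v <- numeric(K)
  swl <- vector("list", K)
  for (k in seq_len(K)) {
    swl[[k]] <- per_class_sw(Y[, k])
    lam <- auto_lambda(Y[, k], if (class_weights == "balanced" ||
                                   !is.null(sample_weights)) swl[[k]] else NULL)
    l1v[k] <- if (is.null(lambda1)) lam[1] else lambda1
    l2v[k] <- if (is.null(lambda2)) lam[2] else lambda2
  }
  uniform_sw <- class_weights == "none" && is.null(sample_weights)
  if (loss == "hinge" || !uniform_sw) {
    # per-class solve (hinge has its own solver; unequal sample weights
    # break the shared-design batching)
    W <- matrix(0, ncol(X), K); b <- numeric(K)
    conv <- logical(K); iters <- integer(K)
    for (k in seq_len(K)) {
      m <- suppressWarnings(
        fit_binary(X, Y[, k], loss, regularizer, l1v[k], l2v[k], groups,
                   control, if (uniform_sw) NULL else swl[[k]]))
      W[, k] <- m$weights; b[k] <- m$intercept
      conv[k] <- m$converged; iters[k] <- m$n_iter
    }
  } else {
    fit <- fista_solve(X, Y, loss, regularizer, l1v, l2v, groups, control)
    W <- fit$W; b <- fit$b
    conv <- rep(fit$converged, K); iters <- rep(fit$n_iter, K)
  }
  structure(list(classes = classes, W = W, b = b, loss = loss,
                 regularizer = regularizer, lambda1 = l1v, lambda2 = l2v,
                 converged = conv, n_iter = iters,
                 class_weights = class_weights),
            class = "ovr_model")
}

#' @export
print.ovr_model <- function(x, ...) {
  cat(sprintf("<ovr_model %s + %s: %d classes (%s), %d features>\n",
              x$loss, x$regularizer, length(x$classes),
              paste(range(x$classes), collapse = "-"), nrow(x$W)))
  invisible(x)
}

#' @param object An `ovr_model`.
#' @param newdata Matrix of feature rows.
#' @param type `"class"` for predicted labels, `"decision"` for the
#'   `n x K` decision-value matrix.
#' @param ... Unused.
#' @rdname fit_one_vs_rest
#' @export
predict.ovr_model <- function(object, newdata, type = c("class", "decision"),
                              ...) {
  type <- match.arg(type)
  D <- as.matrix(newdata) %*% object$W
  D <- sweep(D, 2L, object$b, `+`)
  colnames(D) <- object$classes
  if (type == "decision") return(D)
  # ties.method = "first": ties resolve to the smallest class label
  object$classes[max.col(D, ties.method = "first")]
}
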