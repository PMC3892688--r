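# Independent numeric oracles used to cross-check the package's solvers.
# They share nothing with the implementation path: objectives are written
# out directly and minimized with stats::optim (BFGS, analytic gradients)
# on an epsilon-smoothed surrogate, tightening epsilon in a continuation
# loop.

# direct (non-smoothed) objective of a fitted configuration
reg_objective <- function(w, b, X, y, loss, regularizer, lambda1, lambda2,
                          groups = NULL, penalize_intercept = FALSE) {
  eta <- drop(X %*% w) + b
  lv <- switch(loss,
    least_square = mean((eta - y)^2),
    logistic = mean(log1p(exp(-y * eta))),
    hinge = mean(pmax(0, 1 - y * eta)))
  grp_norm <- function(v) sum(vapply(groups, function(g) sqrt(sum(v[g]^2)),
                                     numeric(1)))
  pen <- switch(regularizer,
    l2 = lambda1 * (sum(w^2) + if (penalize_intercept) b^2 else 0),
    l1 = lambda1 * sum(abs(w)),
    group = lambda2 * grp_norm(w),
    sparse_group = lambda1 * sum(abs(w)) + lambda2 * grp_norm(w))
  lv + pen
}

# general-purpose convex minimizer: BFGS with smoothing continuation
oracle_minimize <- function(X, y, loss, regularizer, lambda1, lambda2,
                            groups = NULL, penalize_intercept = FALSE) {
  d <- ncol(X)
  n <- nrow(X)
  fn <- function(par, eps) {
    w <- par[seq_len(d)]; b <- par[d + 1]
    eta <- drop(X %*% w) + b
    lv <- switch(loss,
      least_square = mean((eta - y)^2),
      logistic = mean(log1p(exp(-y * eta))),
      hinge = { z <- 1 - y * eta; mean((z + sqrt(z^2 + eps^2)) / 2) })
    sabs <- function(v) sqrt(v^2 + eps^2) - eps
    snrm <- function(v) sqrt(sum(v^2) + eps^2) - eps
    grp <- function(v) sum(vapply(groups, function(g) snrm(v[g]), numeric(1)))
    pen <- switch(regularizer,
      l2 = lambda1 * (sum(w^2) + if (penalize_intercept) b^2 else 0),
      l1 = lambda1 * sum(sabs(w)),
      group = lambda2 * grp(w),
      sparse_group = lambda1 * sum(sabs(w)) + lambda2 * grp(w))
    lv + pen
  }
  gr <- function(par, eps) {
    w <- par[seq_len(d)]; b <- par[d + 1]
    eta <- drop(X %*% w) + b
    dl_deta <- switch(loss,
      least_square = 2 * (eta - y) / n,
      logistic = (-y / (1 + exp(y * eta))) / n,
      hinge = { z <- 1 - y * eta
                (-y) * (1 + z / sqrt(z^2 + eps^2)) / (2 * n) })
    g_loss <- c(drop(crossprod(X, dl_deta)), sum(dl_deta))
    dpen_w <- switch(regularizer,
      l2 = 2 * lambda1 * w,
      l1 = lambda1 * w / sqrt(w^2 + eps^2),
      group = {
        out <- numeric(d)
        for (g in groups) out[g] <- lambda2 * w[g] / sqrt(sum(w[g]^2) + eps^2)
        out
      },
      sparse_group = {
        out <- lambda1 * w / sqrt(w^2 + eps^2)
        for (g in groups) out[g] <- out[g] +
          lambda2 * w[g] / sqrt(sum(w[g]^2) + eps^2)
        out
      })
    dpen_b <- if (regularizer == "l2" && penalize_intercept)
      2 * lambda1 * par[d + 1] else 0
    g_loss + c(dpen_w, dpen_b)
  }
  par <- rep(0, d + 1)
  for (eps in c(1e-3, 1e-5, 1e-7, 1e-9)) {
    par <- stats::optim(par, fn, gr, eps = eps, method = "BFGS",
                        control = list(maxit = 5000, reltol = 1e-15))$par
  }
  list(w = par[seq_len(d)], b = par[d + 1],
       objective = reg_objective(par[seq_len(d)], par[d + 1], X, y, loss,
                                 regularizer, lambda1, lambda2, groups,
                                 penalize_intercept))
}

# numeric proximal-operator oracle: minimize 0.5*||u - v||^2 + penalty(u)
# by BFGS with smoothing continuation and analytic gradients
oracle_prox <- function(v, t1, t2, groups = NULL) {
  d <- length(v)
  fn <- function(u, eps) {
    val <- 0.5 * sum((u - v)^2) + t1 * sum(sqrt(u^2 + eps^2) - eps)
    if (!is.null(groups) && t2 > 0) {
      val <- val + t2 * sum(vapply(groups, function(g)
        sqrt(sum(u[g]^2) + eps^2) - eps, numeric(1)))
    }
    val
  }
  gr <- function(u, eps) {
    g <- (u - v) + t1 * u / sqrt(u^2 + eps^2)
    if (!is.null(groups) && t2 > 0) {
      for (gg in groups) g[gg] <- g[gg] + t2 * u[gg] /
          sqrt(sum(u[gg]^2) + eps^2)
    }
    g
  }
  u <- v
  for (eps in c(1e-4, 1e-6, 1e-8, 1e-10)) {
    u <- stats::optim(u, fn, gr, eps = eps, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))$par
  }
  u
}

# small random binary classification instance
random_instance <- function(n = 30, d = 12, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n)
  y <- sign(rnorm(n)); y[y == 0] <- 1
  # ensure both classes
  if (all(y == y[1])) y[1] <- -y[1]
  groups <- split(seq_len(d), rep(seq_len(ceiling(d / 3)), each = 3,
                                  length.out = d))
  list(X = X, y = y, groups = unname(groups))
}
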