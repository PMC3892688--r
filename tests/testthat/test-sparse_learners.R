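test_that("loss values and gradients are exact", {
  inst <- random_instance(n = 5, d = 8, seed = 21)
  X <- inst$X; y <- inst$y
  # zero weights, logistic: every sample contributes log 2
  lz <- loss_value_grad("logistic", rep(0, 8), 0, X, y)
  expect_equal(lz$value, log(2))
  # perfect least-square fit has zero loss
  w <- rep(0, 8); b <- 0
  expect_equal(loss_value_grad("least_square", w, y[1] * 0, X, y * 0)$value, 0)
  # central-difference gradient check
  for (loss in c("least_square", "logistic")) {
    set.seed(31)
    w <- rnorm(8); b <- rnorm(1)
    an <- loss_value_grad(loss, w, b, X, y)$grad
    num <- numeric(9)
    h <- 1e-6
    for (j in 1:9) {
      wp <- w; wm <- w; bp <- b; bm <- b
      if (j <= 8) { wp[j] <- w[j] + h; wm[j] <- w[j] - h }
      else { bp <- b + h; bm <- b - h }
      num[j] <- (loss_value_grad(loss, wp, bp, X, y)$value -
                 loss_value_grad(loss, wm, bm, X, y)$value) / (2 * h)
    }
    expect_equal(an, num, tolerance = 1e-5)
  }
})

test_that("proximal operators match their closed forms and numeric oracles", {
  expect_equal(prox_l1(2.0, 0.5), 1.5)
  expect_equal(prox_l1(0.3, 0.5), 0)
  expect_equal(prox_l1(c(-2, 0.1), 0.5), c(-1.5, 0))
  expect_error(prox_l1(1, -0.1), "nonnegative")

  groups2 <- list(1:2)
  expect_equal(prox_group(c(3, 4), 1, groups2), c(2.4, 3.2))
  expect_equal(prox_group(c(0.54, 0.72), 1, groups2), c(0, 0)) # norm 0.9
  set.seed(7)
  v <- rnorm(6)
  gr <- list(1:3, 4:6)
  expect_equal(prox_group(v, 0, gr), v)

  # numeric prox oracles
  expect_equal(prox_l1(v, 0.4), oracle_prox(v, 0.4, 0), tolerance = 1e-8)
  expect_equal(prox_group(v, 0.6, gr), oracle_prox(v, 0, 0.6, gr),
               tolerance = 1e-6)
  expect_equal(prox_sparse_group(v, 0.3, 0.5, gr),
               oracle_prox(v, 0.3, 0.5, gr), tolerance = 1e-6)
})

test_that("the sparse-group prox degenerates exactly to its two parents", {
  set.seed(8)
  v <- rnorm(12)
  gr <- list(1:4, 5:8, 9:12)
  expect_identical(prox_sparse_group(v, 0.7, 0, gr), prox_l1(v, 0.7))
  expect_identical(prox_sparse_group(v, 0, 0.7, gr), prox_group(v, 0.7, gr))
})

test_that("lambda_max zeroes the Lasso solution at and above the threshold", {
  inst <- random_instance(n = 40, d = 15, seed = 3)
  for (loss in c("least_square", "logistic")) {
    lmx <- lambda_max(inst$X, inst$y, loss, "l1")
    m <- fit_binary(inst$X, inst$y, loss, "l1", lambda1 = lmx * 1.0001,
                    control = solver_control(max_iter = 2000, tol = 1e-10))
    expect_equal(sum(m$weights != 0), 0L)
    # just below the threshold some weight should activate
    m2 <- fit_binary(inst$X, inst$y, loss, "l1", lambda1 = lmx * 0.8,
                     control = solver_control(max_iter = 2000, tol = 1e-10))
    expect_gt(sum(m2$weights != 0), 0L)
  }
})

test_that("all seven configurations match an independent convex minimizer", {
  # several random instances per configuration; objectives must agree to
  # 1e-5 relative
  configs <- list(
    list(loss = "hinge", reg = "l2"),
    list(loss = "least_square", reg = "l1"),
    list(loss = "logistic", reg = "l1"),
    list(loss = "least_square", reg = "group"),
    list(loss = "logistic", reg = "group"),
    list(loss = "least_square", reg = "sparse_group"),
    list(loss = "logistic", reg = "sparse_group"))
  ctrl <- solver_control(max_iter = 20000, tol = 1e-13)
  for (seed in c(101, 202, 303)) {
    inst <- random_instance(n = 30, d = 12, seed = seed)
    for (cf in configs) {
      base_loss <- if (cf$loss == "hinge") "logistic" else cf$loss
      lmx <- lambda_max(inst$X, inst$y, base_loss,
                        if (cf$reg == "group") "group" else "l1",
                        inst$groups)
      l1 <- if (cf$reg %in% c("l1", "sparse_group", "l2")) 0.05 * lmx else 0
      l2 <- if (cf$reg %in% c("group", "sparse_group")) 0.05 * lmx else 0
      m <- suppressWarnings(
        fit_binary(inst$X, inst$y, cf$loss, cf$reg, l1, l2, inst$groups,
                   ctrl))
      pen_b <- cf$loss == "hinge" # SVM carries the bias in the penalty
      got <- reg_objective(m$weights, m$intercept, inst$X, inst$y, cf$loss,
                           cf$reg, l1, l2, inst$groups, pen_b)
      oracle <- oracle_minimize(inst$X, inst$y, cf$loss, cf$reg, l1, l2,
                                inst$groups, pen_b)
      expect_lt((got - oracle$objective) / abs(oracle$objective), 1e-5)
    }
  }
})

test_that("lasso objective agrees with glmnet on matched problems", {
  skip_if_not_installed("glmnet")
  inst <- random_instance(n = 50, d = 20, seed = 77)
  # gaussian: glmnet minimizes (1/2n)RSS + lambda ||w||_1 = ours / 2
  lmx <- lambda_max(inst$X, inst$y, "least_square", "l1")
  l1 <- 0.1 * lmx
  m <- fit_binary(inst$X, inst$y, "least_square", "l1", l1,
                  control = solver_control(max_iter = 20000, tol = 1e-13))
  g <- glmnet::glmnet(inst$X, inst$y, family = "gaussian", lambda = l1 / 2,
                      standardize = FALSE, thresh = 1e-14)
  ours <- reg_objective(m$weights, m$intercept, inst$X, inst$y,
                        "least_square", "l1", l1, 0)
  theirs <- reg_objective(as.numeric(g$beta), as.numeric(g$a0), inst$X,
                          inst$y, "least_square", "l1", l1, 0)
  expect_lt(abs(ours - theirs) / theirs, 1e-6)
  # binomial: identical objective parameterization at lambda = l1
  lmxb <- lambda_max(inst$X, inst$y, "logistic", "l1")
  l1b <- 0.1 * lmxb
  mb <- fit_binary(inst$X, inst$y, "logistic", "l1", l1b,
                   control = solver_control(max_iter = 20000, tol = 1e-13))
  gb <- glmnet::glmnet(inst$X, ifelse(inst$y > 0, 1, 0),
                       family = "binomial", lambda = l1b,
                       standardize = FALSE, thresh = 1e-14)
  ours_b <- reg_objective(mb$weights, mb$intercept, inst$X, inst$y,
                          "logistic", "l1", l1b, 0)
  theirs_b <- reg_objective(as.numeric(gb$beta), as.numeric(gb$a0), inst$X,
                            inst$y, "logistic", "l1", l1b, 0)
  expect_lt(abs(ours_b - theirs_b) / theirs_b, 1e-5)
})

test_that("the accepted objective sequence is non-increasing", {
  inst <- random_instance(n = 40, d = 15, seed = 12)
  lmx <- lambda_max(inst$X, inst$y, "logistic", "l1")
  m <- fit_binary(inst$X, inst$y, "logistic", "l1", 0.05 * lmx,
                  control = solver_control(max_iter = 300, tol = 1e-12))
  # monotone-safeguarded FISTA: every accepted objective is <= the last
  tr <- m$obj_trace
  expect_gt(length(tr), 10L)
  expect_true(all(diff(tr) <= 1e-12))
  expect_lt(tr[length(tr)], tr[1])
})

test_that("group penalties zero or keep whole groups together", {
  inst <- random_instance(n = 30, d = 12, seed = 14)
  lmx <- lambda_max(inst$X, inst$y, "least_square", "group", inst$groups)
  m <- fit_binary(inst$X, inst$y, "least_square", "group", 0, 0.5 * lmx,
                  inst$groups, solver_control(max_iter = 5000, tol = 1e-12))
  status <- vapply(inst$groups, function(g) {
    nz <- m$weights[g] != 0
    all(nz) || all(!nz)
  }, logical(1))
  expect_true(all(status))
  # and at least one group must be dropped at this strength
  dropped <- vapply(inst$groups, function(g) all(m$weights[g] == 0),
                    logical(1))
  expect_gt(sum(dropped), 0L)
})

test_that("separable problems are fit perfectly and OvR follows its contracts", {
  # separable 2-D toy data
  set.seed(15)
  X <- rbind(matrix(rnorm(40, mean = 2, sd = 0.3), 20),
             matrix(rnorm(40, mean = -2, sd = 0.3), 20))
  y <- rep(c(1, -1), each = 20)
  m <- fit_binary(X, y, "logistic", "l2", lambda1 = 1e-4)
  expect_equal(mean(predict(m, X, type = "class") == y), 1)

  # 15-class labels produce exactly 15 binary models
  bl <- blob_data(n_per_class = 3, classes = 3:17, d = 16, sd = 0.05)
  ovr <- suppressWarnings(
    fit_one_vs_rest(bl$X, bl$y, "least_square", "l2", lambda1 = 1e-3,
                    control = solver_control(max_iter = 200)))
  expect_identical(ovr$classes, 3:17)
  expect_identical(ncol(ovr$W), 15L)

  # all-equal decision values tie-break to the smallest stage
  fake <- ovr
  fake$W[] <- 0; fake$b[] <- 0.7
  expect_identical(predict(fake, matrix(0, 1, 16)), 3L)

  # well-separated blobs are classified essentially perfectly
  bl3 <- blob_data(n_per_class = 30, classes = c(4L, 9L, 14L), d = 10,
                   sd = 0.3, seed = 44)
  ovr3 <- fit_one_vs_rest(bl3$X, bl3$y, "logistic", "l1")
  expect_gte(mean(predict(ovr3, bl3$X) == bl3$y), 0.95)
})

test_that("invalid training inputs are rejected", {
  inst <- random_instance()
  expect_error(fit_binary(inst$X, rep(1, nrow(inst$X)), "logistic", "l1"),
               "both classes")
  expect_error(fit_binary(inst$X, inst$y * 2, "logistic", "l1"),
               "\\{-1, \\+1\\}")
  expect_error(fit_binary(inst$X, inst$y, "hinge", "l1"), "l2")
  expect_error(fit_binary(inst$X, inst$y, "logistic", "group",
                          lambda2 = 0.1, groups = list(1:3)),
               "partition")
})
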