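test_that("pool specs count members multiplicatively", {
  expect_equal(pool_size(pool_spec()), 1050L)
  expect_equal(pool_size(pool_spec(algorithms = "lasso_logistic",
                                   ratios = 0.7, n_partitions = 1)), 1L)
  expect_equal(pool_size(pool_spec(ratios = c(0.7, 0.8),
                                   n_partitions = 3)), 42L)
  expect_error(pool_spec(algorithms = "boost"), "'arg'")
  expect_error(pool_spec(ratios = 1.2))
})

test_that("voting accumulates confidence-weighted one-hot predictions", {
  pool <- scripted_pool(stages_predicted = c(10L, 10L, 9L),
                        confidences = c(0.8, 0.7, 0.6))
  H <- pool_vote(pool, matrix(0, 1, 4))
  expect_equal(unname(H[1, "10"]), 1.5)
  expect_equal(unname(H[1, "9"]), 0.6)
  expect_equal(sum(H[1, c("9", "10")]), sum(H))
  # single member: one-hot scaled by its confidence
  p1 <- scripted_pool(12L, 0.45)
  H1 <- pool_vote(p1, matrix(0, 1, 4))
  expect_equal(as.numeric(H1), ifelse(3:17 == 12, 0.45, 0))
  # dimension mismatch caught
  expect_error(pool_vote(pool, matrix(0, 1, 7)), "expect")
})

test_that("vote mass is conserved: row sums equal total active confidence", {
  set.seed(61)
  conf <- runif(25)
  pred <- sample(3:17, 25, replace = TRUE)
  pool <- scripted_pool(pred, conf)
  X <- matrix(rnorm(100 * 4), 100)
  H <- pool_vote(pool, X)
  expect_equal(rowSums(H), rep(sum(conf), 100), tolerance = 1e-12)
})

test_that("histogram annotation follows the declared stage-score convention", {
  H <- rep(0, 15); names(H) <- 3:17
  # stage 10 wins; early neighbour heavier -> E, score below 10
  H[match(c(9, 10, 11), 3:17)] <- c(4, 6, 1)
  a <- annotate_histogram(H)
  expect_equal(a$stage, 10L)
  expect_equal(a$substage, "E")
  expect_equal(a$stage_score, 10 + 0.5 * (1 - 4) / 5) # = 9.7
  # symmetric neighbours: exactly S, substage ties to L
  H[match(c(9, 11), 3:17)] <- c(2, 2)
  a <- annotate_histogram(H)
  expect_equal(a$stage_score, 10)
  expect_equal(a$substage, "L")
  # empty neighbours: score = S
  H2 <- rep(0, 15); H2[match(8, 3:17)] <- 3
  expect_equal(annotate_histogram(H2)$stage_score, 8)
  # edge stages carry no refinement
  H3 <- rep(0, 15); H3[1] <- 2; H3[2] <- 1
  a3 <- annotate_histogram(H3)
  expect_equal(a3$stage, 3L)
  expect_true(is.na(a3$substage) && is.na(a3$stage_score))
  # argmax ties break to the smaller stage
  H4 <- rep(1, 15)
  expect_equal(annotate_histogram(H4)$stage, 3L)
  expect_error(annotate_histogram(rep(0, 15)), "all-zero")
})

test_that("stage scores stay within half a stage and increase with late votes", {
  for (hi in seq(0, 5, by = 0.5)) {
    H <- rep(0, 15)
    H[match(c(9, 10, 11), 3:17)] <- c(2, 7, hi)
    a <- annotate_histogram(H)
    expect_gte(a$stage_score, 9.5)
    expect_lte(a$stage_score, 10.5)
  }
  scores <- sapply(seq(0, 5, by = 0.5), function(hi) {
    H <- rep(0, 15)
    H[match(c(9, 10, 11), 3:17)] <- c(2, 7, hi)
    annotate_histogram(H)$stage_score
  })
  expect_true(all(diff(scores) > 0))
})

test_that("thirds split cohorts evenly, remainder first, order-invariantly", {
  ann <- data.frame(
    image = sprintf("i%02d", 1:13),
    stage = c(rep(10L, 6), rep(10L, 7)),
    substage = c(rep("E", 6), rep("L", 7)),
    stage_score = c(9.9, 9.6, 9.8, 9.55, 9.7, 9.75,
                    10.1, 10.45, 10.2, 10.3, 10.15, 10.4, 10.25),
    stringsAsFactors = FALSE)
  out <- assign_thirds(ann)
  e <- out[out$substage == "E", ]
  expect_equal(table(e$third), table(c("a", "a", "b", "b", "c", "c")))
  l <- out[out$substage == "L", ]
  expect_equal(as.numeric(table(l$third)), c(3, 2, 2)) # remainder to front
  # the lowest scores get "a"
  expect_equal(sort(e$stage_score[e$third == "a"]), c(9.55, 9.6))
  # permutation invariance
  perm <- sample(nrow(ann))
  out2 <- assign_thirds(ann[perm, ])
  expect_equal(out2$third[match(out$image, out2$image)], out$third)
  # tiny cohorts get a, b, c by rank
  small <- data.frame(image = c("a", "b"), stage = 7L, substage = "E",
                      stage_score = c(7.2, 6.9), stringsAsFactors = FALSE)
  o <- assign_thirds(small)
  expect_equal(o$third, c("b", "a"))
  # edge stages get no third
  edge <- data.frame(image = "z", stage = 3L, substage = NA_character_,
                     stage_score = NA_real_, stringsAsFactors = FALSE)
  expect_true(is.na(assign_thirds(edge)$third))
})

test_that("disagreement rate counts splits where algorithms differ", {
  # two 'algorithms' on one shared split: scripted by hand
  mk <- function(stages) scripted_pool(stages, rep(1, length(stages)))
  p <- mk(c(10L, 10L))
  p$members[[1]]$algorithm <- "lasso_ls"
  p$members[[2]]$algorithm <- "svm_hinge_l2"
  p$members[[2]]$partition <- 1 # same split as member 1
  p$spec$algorithms <- c("lasso_ls", "svm_hinge_l2")
  X <- matrix(0, 3, 4)
  expect_equal(disagreement_rate(p, X), 0)
  # now make them always differ
  p$members[[2]]$model$b[match(10L, 3:17)] <- 0
  p$members[[2]]$model$b[match(9L, 3:17)] <- 1
  expect_equal(disagreement_rate(p, X), 1)
  expect_error(disagreement_rate(scripted_pool(10L, 1), X),
               "single-algorithm")
})

test_that("trained pools have the declared size, provenance and determinism", {
  bl <- blob_data(n_per_class = 8, classes = c(5L, 9L, 13L), d = 12,
                  sd = 0.4, seed = 5)
  spec <- pool_spec(algorithms = c("lasso_logistic", "svm_hinge_l2"),
                    ratios = c(0.6, 0.8), n_partitions = 2, master_seed = 31)
  ctrl <- solver_control(max_iter = 150, tol = 1e-6)
  pool <- build_pool(bl$X, bl$y, spec, groups = list_groups(12),
                     control = ctrl)
  expect_s3_class(pool, "model_pool")
  expect_length(pool$members, 8L)
  conf <- vapply(pool$members, `[[`, numeric(1), "confidence")
  expect_true(all(conf >= 0 & conf <= 1))
  prov <- unique(vapply(pool$members, function(m)
    paste(m$algorithm, m$ratio, m$partition), character(1)))
  expect_length(prov, 8L)
  # determinism: identical master seed, identical pool behaviour
  pool2 <- build_pool(bl$X, bl$y, spec, groups = list_groups(12),
                      control = ctrl)
  expect_identical(vapply(pool2$members, `[[`, numeric(1), "confidence"),
                   conf)
  X <- bl$X[1:5, ]
  expect_identical(pool_vote(pool, X), pool_vote(pool2, X))
  # disagreement rate on real trained members is a fraction
  dr <- disagreement_rate(pool, bl$X)
  expect_gte(dr, 0); expect_lte(dr, 1)
})

test_that("pools round-trip through the archive format", {
  bl <- blob_data(n_per_class = 6, classes = c(6L, 11L), d = 8, sd = 0.4,
                  seed = 6)
  spec <- pool_spec(algorithms = c("lasso_ls", "group_logistic"),
                    ratios = 0.7, n_partitions = 1, master_seed = 2)
  pool <- build_pool(bl$X, bl$y, spec, groups = list_groups(8),
                     control = solver_control(max_iter = 100))
  dir <- file.path(tempdir(), "pool_archive")
  save_pool(pool, dir)
  pool2 <- load_pool(dir)
  X <- bl$X[1:4, ]
  expect_equal(pool_vote(pool2, X), pool_vote(pool, X))
  ann1 <- annotate_images(pool, X)
  ann2 <- annotate_images(pool2, X)
  expect_equal(ann1[, c("stage", "substage", "stage_score")],
               ann2[, c("stage", "substage", "stage_score")])
})
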