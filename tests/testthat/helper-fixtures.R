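# Small shared fixtures, built once per test run.

# tiny noise-free corpus spanning all 15 stages (2 images each)
tiny_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_corpus(synthetic_spec(n_per_stage = 2,
                                               noise_sd = 0, seed = 424))
    }
    cache
  }
})

# low-dimensional separable multiclass problem standing in for Gabor
# features: class centers on a line, tight gaussian blobs
blob_data <- function(n_per_class = 20, classes = c(3L, 8L, 13L), d = 10,
                      sd = 0.3, seed = 99) {
  set.seed(seed)
  X <- NULL; y <- integer(0)
  for (k in seq_along(classes)) {
    center <- rep(0, d); center[k] <- 3
    X <- rbind(X, matrix(rnorm(n_per_class * d, sd = sd), n_per_class) +
                 matrix(center, n_per_class, d, byrow = TRUE))
    y <- c(y, rep(classes[k], n_per_class))
  }
  list(X = X, y = y)
}

# trivial contiguous group structure for low-dimensional test problems
list_groups <- function(d, size = 4L) {
  unname(split(seq_len(d), rep(seq_len(ceiling(d / size)), each = size,
                               length.out = d)))
}

# hand-built pool whose members always predict a scripted stage with a
# scripted confidence, for voting arithmetic tests
scripted_pool <- function(stages_predicted, confidences, d = 4L) {
  classes <- 3:17
  members <- lapply(seq_along(stages_predicted), function(i) {
    b <- rep(0, length(classes))
    b[match(stages_predicted[i], classes)] <- 1
    model <- structure(list(classes = classes,
                            W = matrix(0, d, length(classes)), b = b,
                            loss = "logistic", regularizer = "l1",
                            lambda1 = 0, lambda2 = 0,
                            converged = TRUE, n_iter = 0L,
                            class_weights = "none"),
                       class = "ovr_model")
    list(algorithm = "lasso_logistic", ratio = 0.5, partition = i,
         model = model, mu = rep(0, d), sd = rep(1, d),
         confidence = confidences[i], excluded = FALSE)
  })
  structure(list(spec = pool_spec(algorithms = "lasso_logistic",
                                  ratios = 0.5,
                                  n_partitions = length(members)),
                 classes = classes, n_features = d, members = members),
            class = "model_pool")
}
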