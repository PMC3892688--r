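#' The seven pool algorithm configurations
#'
#' Names map onto (loss, regularizer) pairs: a linear hinge-loss SVM plus
#' the six sparse learners (Lasso, group Lasso, sparse group Lasso, each
#' with least-square and logistic loss).
#' @export
POOL_ALGORITHMS <- c("svm_hinge_l2", "lasso_ls", "lasso_logistic",
                     "group_ls", "group_logistic",
                     "sparse_group_ls", "sparse_group_logistic")

algorithm_config <- function(name) {
  switch(name,
    svm_hinge_l2 = list(loss = "hinge", regularizer = "l2"),
    lasso_ls = list(loss = "least_square", regularizer = "l1"),
    lasso_logistic = list(loss = "logistic", regularizer = "l1"),
    group_ls = list(loss = "least_square", regularizer = "group"),
    group_logistic = list(loss = "logistic", regularizer = "group"),
    sparse_group_ls = list(loss = "least_square", regularizer = "sparse_group"),
    sparse_group_logistic = list(loss = "logistic", regularizer = "sparse_group"),
    stop("unknown algorithm: ", name)
  )
}

#' Specify a classifier pool
#'
#' A pool crosses classification algorithms with random train/validation
#' partitions of the labelled data: for each training ratio,
#' `n_partitions` stratified random splits are drawn, and every algorithm
#' is trained on every split. The full-size configuration (7 algorithms x
#' 5 ratios x 30 partitions) yields 1050 members. Partitions are shared
#' across algorithms within each (ratio, partition) cell so that algorithm
#' disagreement is measured on identical splits.
#'
#' @param algorithms Subset of [POOL_ALGORITHMS].
#' @param ratios Training-set fractions in (0, 1).
#' @param n_partitions Random partitions per ratio.
#' @param master_seed Integer seed from which every split and solver
#'   randomization is derived.
#' @return A `pool_spec`.
#' @export
pool_spec <- function(algorithms = POOL_ALGORITHMS,
                      ratios = seq(0.5, 0.9, by = 0.1),
                      n_partitions = 30L, master_seed = 1L) {
  algorithms <- match.arg(algorithms, POOL_ALGORITHMS, several.ok = TRUE)
  stopifnot(all(ratios > 0 & ratios < 1), n_partitions >= 1L)
  structure(list(algorithms = algorithms, ratios = ratios,
                 n_partitions = as.integer(n_partitions),
                 master_seed = as.integer(master_seed)),
            class = "pool_spec")
}

#' @export
print.pool_spec <- function(x, ...) {
  cat(sprintf("<pool_spec: %d algorithms x %d ratios x %d partitions = %d members, seed %d>\n",
              length(x$algorithms), length(x$ratios), x$n_partitions,
              pool_size(x), x$master_seed))
  invisible(x)
}

#' Number of members a pool specification generates
#' @param spec A [pool_spec()].
#' @return Integer member count.
#' @export
pool_size <- function(spec) {
  length(spec$algorithms) * length(spec$ratios) * spec$n_partitions
}

# run code with a locally-seeded RNG, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# stratified train/validation split: per class, a shuffled split keeping
# at least one sample on each side
stratified_split <- function(y, ratio) {
  train <- integer(0)
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    n_tr <- max(1L, min(length(idx) - 1L, round(ratio * length(idx))))
    # sample.int: safe for length-1 idx (sample(idx) would permute 1:idx)
    train <- c(train, idx[sample.int(length(idx))][seq_len(n_tr)])
  }
  sort(train)
}

#' Build a pool of diverse one-vs-rest classifiers
#'
#' For every (ratio, partition) cell a stratified random train/validation
#' split is drawn (deterministically from `master_seed`); every algorithm
#' in the spec is trained on the training part; the member's confidence is
#' its multiclass accuracy on the validation part. Features are z-scored
#' per split (training mean/sd, applied to validation and later inputs) so
#' the penalized solvers see comparable feature scales.
#'
#' Members whose training part lost a class entirely are flagged
#' `excluded` and contribute nothing to voting. Members with an empty
#' validation part fall back to their training accuracy as confidence.
#'
#' @param X `n x d` feature matrix.
#' @param y Integer stage labels (3..17).
#' @param spec A [pool_spec()].
#' @param groups Feature group partition (for the group penalties);
#'   defaults to the standard Gabor region structure when `d` matches.
#' @param control Solver settings for pool training. The default caps the
#'   proximal solvers at 200 iterations (tolerance 1e-5): pool members are
#'   deliberately many and approximate, and ensemble voting does not
#'   reward solving each member to high precision.
#' @param svm_control Solver settings for the hinge-loss members, whose
#'   dual solver stops on the projected-gradient norm; the default
#'   tolerance (0.01) follows standard linear-SVM practice, where much
#'   looser duality gaps than proximal objective tolerances give the same
#'   classifier.
#' @param lambda_scale,class_weights Passed to [fit_one_vs_rest()].
#' @param standardize Per-split feature z-scoring (default `TRUE`).
#' @param verbose Progress messages.
#' @return A `model_pool`: the spec, the class alphabet, and one member
#'   record per (algorithm, ratio, partition) with model, scaler,
#'   confidence and provenance.
#' @export
build_pool <- function(X, y, spec = pool_spec(), groups = NULL,
                       control = solver_control(max_iter = 200L, tol = 1e-5),
                       svm_control = solver_control(max_iter = 100L, tol = 0.01),
                       lambda_scale = 0.01,
                       class_weights = "none",
                       standardize = TRUE, verbose = FALSE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  classes <- sort(unique(y))
  counts <- tabulate(match(y, classes))
  if (any(counts < 2L)) {
    warning("stages with fewer than 2 samples: ",
            paste(classes[counts < 2L], collapse = ", "))
  }
  if (is.null(groups) && ncol(X) %% 640L == 0L) {
    groups <- gabor_group_structure(ncol(X) %/% 640L, 640L)
  }
  members <- list()
  with_seed(spec$master_seed, {
    # all splits drawn up-front so the split sequence is independent of
    # which algorithms run
    splits <- list()
    for (ri in seq_along(spec$ratios)) {
      for (pi in seq_len(spec$n_partitions)) {
        splits[[paste(ri, pi)]] <- stratified_split(y, spec$ratios[ri])
      }
    }
    for (ri in seq_along(spec$ratios)) {
      for (pi in seq_len(spec$n_partitions)) {
        tr <- splits[[paste(ri, pi)]]
        va <- setdiff(seq_len(nrow(X)), tr)
        Xtr <- X[tr, , drop = FALSE]
        ytr <- y[tr]
        excluded_split <- !setequal(unique(ytr), classes)
        if (standardize) {
          mu <- colMeans(Xtr)
          sd <- sqrt(colMeans(Xtr^2) - mu^2)
          sd[sd < 1e-12] <- 1
        } else {
          mu <- rep(0, ncol(X)); sd <- rep(1, ncol(X))
        }
        Xtr_s <- scale_features(Xtr, mu, sd)
        Xva_s <- scale_features(X[va, , drop = FALSE], mu, sd)
        for (alg in spec$algorithms) {
          cfg <- algorithm_config(alg)
          if (excluded_split) {
            members[[length(members) + 1L]] <- list(
              algorithm = alg, ratio = spec$ratios[ri], partition = pi,
              model = NULL, mu = mu, sd = sd, confidence = 0,
              excluded = TRUE)
            next
          }
          model <- suppressWarnings(
            fit_one_vs_rest(Xtr_s, ytr, loss = cfg$loss,
                            regularizer = cfg$regularizer, groups = groups,
                            lambda_scale = lambda_scale,
                            control = if (cfg$loss == "hinge") svm_control
                                      else control,
                            class_weights = class_weights))
          conf <- if (length(va)) {
            mean(predict(model, Xva_s) == y[va])
          } else {
            mean(predict(model, Xtr_s) == ytr)
          }
          if (verbose) {
            message(sprintf("ratio %.1f partition %d %-22s confidence %.3f",
                            spec$ratios[ri], pi, alg, conf))
          }
          members[[length(members) + 1L]] <- list(
            algorithm = alg, ratio = spec$ratios[ri], partition = pi,
            model = model, mu = mu, sd = sd, confidence = conf,
            excluded = FALSE)
        }
      }
    }
  })
  structure(list(spec = spec, classes = classes, n_features = ncol(X),
                 members = members),
            class = "model_pool")
}

scale_features <- function(X, mu, sd) {
  X <- sweep(X, 2L, mu, `-`)
  sweep(X, 2L, sd, `/`)
}

#' @export
print.model_pool <- function(x, ...) {
  ex <- sum(vapply(x$members, `[[`, logical(1), "excluded"))
  conf <- vapply(x$members[!vapply(x$members, `[[`, logical(1), "excluded")],
                 `[[`, numeric(1), "confidence")
  cat(sprintf("<model_pool: %d members (%d excluded), %d classes, %d features>\n",
              length(x$members), ex, length(x$classes), x$n_features))
  if (length(conf)) {
    cat(sprintf("  confidence: median %.3f, range [%.3f, %.3f]\n",
                stats::median(conf), min(conf), max(conf)))
  }
  invisible(x)
}

# per-member stage predictions for a feature matrix; excluded members give NA
pool_predictions <- function(pool, X) {
  X <- as.matrix(X)
  if (ncol(X) != pool$n_features) {
    stop(sprintf("features have %d columns but pool models expect %d",
                 ncol(X), pool$n_features))
  }
  P <- vapply(pool$members, function(m) {
    if (m$excluded) return(rep(NA_integer_, nrow(X)))
    as.integer(predict(m$model, scale_features(X, m$mu, m$sd)))
  }, integer(nrow(X)))
  matrix(P, nrow = nrow(X)) # vapply drops dims for single-row input
}

#' Confidence-weighted voting histogram
#'
#' Every active pool member casts one vote for its predicted stage,
#' weighted by its confidence (validation accuracy), giving the prediction
#' histogram `H(j) = sum_i a_i * p_ij` over the full stage alphabet
#' 3..17. Row sums therefore equal the total active confidence mass.
#'
#' @param pool A `model_pool`.
#' @param X Feature matrix (rows = images) or a single feature vector.
#' @return An `n x 15` matrix of vote weights, columns named "3".."17".
#' @export
pool_vote <- function(pool, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (length(pool$members) == 0L) stop("empty pool")
  P <- pool_predictions(pool, X)
  H <- matrix(0, nrow(X), length(STAGES),
              dimnames = list(rownames(X), STAGES))
  for (i in seq_along(pool$members)) {
    m <- pool$members[[i]]
    if (m$excluded) next
    col <- match(P[, i], STAGES)
    H[cbind(seq_len(nrow(X)), col)] <-
      H[cbind(seq_len(nrow(X)), col)] + m$confidence
  }
  H
}

#' Annotate a voting histogram with stage, sub-stage and stage score
#'
#' The stage `S` is the histogram argmax (ties toward the smaller stage).
#' For interior stages (4..16) the two neighbouring bins refine the call:
#' the image is early (`E`) when `H(S-1) > H(S+1)`, late (`L`) otherwise
#' (a tie counts as late), and the continuous stage score is
#' `SS = S + 0.5 * (H(S+1) - H(S-1)) / (H(S-1) + H(S+1))`, which lies in
#' `[S - 0.5, S + 0.5]` and decreases as the early neighbour gathers
#' relatively more votes; `SS = S` when both neighbours are empty. Edge
#' stages 3 and 17 have no neighbour on one side and receive a stage only.
#'
#' @param H Length-15 vote vector indexed by stages 3..17 (names optional).
#' @return A list with `stage` (integer), `substage` (`"E"`, `"L"` or
#'   `NA`), and `stage_score` (numeric or `NA`).
#' @export
annotate_histogram <- function(H) {
  H <- as.numeric(H)
  if (length(H) != length(STAGES)) {
    stop("histogram must have one entry per stage 3..17")
  }
  if (all(H == 0)) stop("all-zero voting histogram cannot be annotated")
  S <- STAGES[which.max(H)] # which.max: first maximum = smallest stage
  if (S < 4L || S > 16L) {
    return(list(stage = S, substage = NA_character_,
                stage_score = NA_real_))
  }
  lo <- H[match(S - 1L, STAGES)]
  hi <- H[match(S + 1L, STAGES)]
  if (lo + hi == 0) {
    ss <- as.numeric(S)
  } else {
    ss <- S + 0.5 * (hi - lo) / (lo + hi)
  }
  list(stage = S, substage = if (lo > hi) "E" else "L", stage_score = ss)
}

#' Annotate images with the pool
#'
#' Runs [pool_vote()] and [annotate_histogram()] over a feature matrix and
#' returns one annotation row per image, including the three top-voted
#' stages for audit.
#'
#' @param pool A `model_pool`.
#' @param X Feature matrix.
#' @param ids Optional image identifiers (defaults to feature row names).
#' @return A data.frame with columns `image`, `stage`, `substage`,
#'   `stage_score`, `top3_stages`, `top3_votes`.
#' @export
annotate_images <- function(pool, X, ids = NULL) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  H <- pool_vote(pool, X)
  if (is.null(ids)) {
    ids <- if (!is.null(rownames(X))) rownames(X) else
      sprintf("image_%04d", seq_len(nrow(X)))
  }
  ann <- lapply(seq_len(nrow(X)), function(i) annotate_histogram(H[i, ]))
  top3 <- t(apply(H, 1L, function(h) {
    o <- order(-h, STAGES)[1:3]
    c(paste(STAGES[o], collapse = ";"),
      paste(signif(h[o], 6), collapse = ";"))
  }))
  data.frame(image = ids,
             stage = vapply(ann, `[[`, integer(1), "stage"),
             substage = vapply(ann, `[[`, character(1), "substage"),
             stage_score = vapply(ann, `[[`, numeric(1), "stage_score"),
             top3_stages = top3[, 1], top3_votes = top3[, 2],
             stringsAsFactors = FALSE)
}

#' Split sub-stage cohorts into thirds by stage score
#'
#' Within each (stage, substage) cohort, images are sorted by stage score
#' (stable, ties keeping input order) and split evenly into three groups
#' labelled `a`, `b`, `c` in developmental order; when the cohort size is
#' not divisible by 3 the earlier groups take the remainder. Cohorts
#' smaller than 3 are labelled `a`, `b`, `c` by rank as far as available.
#' Images without a sub-stage (stages 3 and 17) get no third.
#'
#' @param annotations Data.frame from [annotate_images()].
#' @return The same data.frame with a `third` column added.
#' @export
assign_thirds <- function(annotations) {
  ann <- annotations
  ann$third <- NA_character_
  key <- paste(ann$stage, ann$substage)
  for (k in unique(key[!is.na(ann$substage)])) {
    rows <- which(key == k & !is.na(ann$substage))
    o <- rows[order(ann$stage_score[rows])] # stable: ties keep input order
    n <- length(o)
    base <- n %/% 3L
    rem <- n %% 3L
    sizes <- base + (seq_len(3L) <= rem)
    labels <- rep(c("a", "b", "c"), times = sizes)
    ann$third[o] <- labels[seq_len(n)]
  }
  ann
}

#' Algorithm disagreement rate over shared splits
#'
#' For every (ratio, partition) cell and every sample, counts 1 when the
#' algorithms trained on that shared split do not all predict the same
#' stage, and averages over samples and cells. A diversity diagnostic for
#' the pool.
#'
#' @param pool A `model_pool` whose spec includes at least 2 algorithms.
#' @param X Feature matrix of evaluation samples.
#' @return Fraction in `[0, 1]`.
#' @export
disagreement_rate <- function(pool, X) {
  if (length(pool$spec$algorithms) < 2L) {
    stop("disagreement rate is undefined for a single-algorithm pool")
  }
  X <- as.matrix(X)
  P <- pool_predictions(pool, X)
  cell <- vapply(pool$members, function(m) paste(m$ratio, m$partition),
                 character(1))
  active <- !vapply(pool$members, `[[`, logical(1), "excluded")
  rates <- c()
  for (cl in unique(cell)) {
    idx <- which(cell == cl & active)
    if (length(idx) < 2L) next
    Pc <- P[, idx, drop = FALSE]
    rates <- c(rates, mean(apply(Pc, 1L, function(p) length(unique(p)) > 1L)))
  }
  if (!length(rates)) stop("no split has 2 or more active algorithms")
  mean(rates)
}

#' Save / load a model pool
#'
#' The pool is written as a directory holding a JSON manifest (spec,
#' classes, per-member provenance, confidence and penalty strengths) and a
#' binary payload with every member's weight matrix, intercepts and
#' feature scaler.
#'
#' @param pool A `model_pool`.
#' @param dir Directory to create/overwrite.
#' @return `dir`, invisibly (`save_pool`); the restored `model_pool`
#'   (`load_pool`).
#' @export
save_pool <- function(pool, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    spec = unclass(pool$spec), classes = pool$classes,
    n_features = pool$n_features,
    members = lapply(pool$members, function(m) {
      out <- m[c("algorithm", "ratio", "partition", "confidence", "excluded")]
      if (!m$excluded) {
        out$lambda1 <- m$model$lambda1
        out$lambda2 <- m$model$lambda2
        out$solver <- if (m$model$loss == "hinge")
          "dual_coordinate_descent" else "fista"
      }
      out
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(file.path(dir, "weights.bin"), "wb")
  on.exit(close(con))
  for (m in pool$members) {
    if (m$excluded) next
    writeBin(as.vector(m$model$W), con, size = 8L, endian = "little")
    writeBin(m$model$b, con, size = 8L, endian = "little")
    writeBin(m$mu, con, size = 8L, endian = "little")
    writeBin(m$sd, con, size = 8L, endian = "little")
  }
  invisible(dir)
}

#' @param dir Directory written by `save_pool`.
#' @rdname save_pool
#' @export
load_pool <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  classes <- as.integer(manifest$classes)
  d <- as.integer(manifest$n_features)
  K <- length(classes)
  con <- file(file.path(dir, "weights.bin"), "rb")
  on.exit(close(con))
  members <- lapply(seq_len(nrow(manifest$members)), function(i) {
    mm <- manifest$members[i, ]
    if (isTRUE(mm$excluded)) {
      return(list(algorithm = mm$algorithm, ratio = mm$ratio,
                  partition = mm$partition, model = NULL,
                  mu = rep(0, d), sd = rep(1, d),
                  confidence = mm$confidence, excluded = TRUE))
    }
    W <- matrix(readBin(con, "double", d * K, size = 8L, endian = "little"),
                d, K)
    b <- readBin(con, "double", K, size = 8L, endian = "little")
    mu <- readBin(con, "double", d, size = 8L, endian = "little")
    sd <- readBin(con, "double", d, size = 8L, endian = "little")
    cfg <- algorithm_config(mm$algorithm)
    model <- structure(list(classes = classes, W = W, b = b,
                            loss = cfg$loss, regularizer = cfg$regularizer,
                            lambda1 = unlist(mm$lambda1),
                            lambda2 = unlist(mm$lambda2),
                            converged = NA, n_iter = NA,
                            class_weights = "none"),
                       class = "ovr_model")
    list(algorithm = mm$algorithm, ratio = mm$ratio,
         partition = mm$partition, model = model, mu = mu, sd = sd,
         confidence = mm$confidence, excluded = FALSE)
  })
  spec <- pool_spec(algorithms = unlist(manifest$spec$algorithms),
                    ratios = unlist(manifest$spec$ratios),
                    n_partitions = manifest$spec$n_partitions,
                    master_seed = manifest$spec$master_seed)
  structure(list(spec = spec, classes = classes, n_features = d,
                 members = members),
            class = "model_pool")
}
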