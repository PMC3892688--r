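#' Half-stage index of a (stage, substage) annotation
#'
#' Maps each annotation onto a half-stage axis:
#' `2*stage` for an early (`E`) call, `2*stage + 1` for a late (`L`) call.
#' The edge stages carry no sub-stage and sit at the position adjacent to
#' their only neighbour: stage 3 at `2*3 + 1` (one half-step below 4E) and
#' stage 17 at `2*17` (one half-step above 16L). Adjacent sub-stages are
#' exactly one apart on this axis. A mid-stage annotation without a
#' sub-stage flag (e.g. reference labels annotated at stage resolution
#' only) sits between its own two halves, at `2*stage + 0.5`: both E and L
#' of the same stage are within one half-step of it, neighbouring stages
#' are not.
#'
#' @param stage Integer stage in 3..17 (vectorized).
#' @param substage `"E"`, `"L"` or `NA`.
#' @return Numeric half-stage index.
#' @export
half_stage_index <- function(stage, substage) {
  stage <- as.integer(stage)
  out <- 2 * stage + ifelse(is.na(substage), 0.5, (substage == "L"))
  out[stage <= 3L] <- 7
  out[stage >= 17L] <- 34
  out
}

#' Sub-stage accuracy indicator
#'
#' 1 when the predicted (stage, substage) pair equals the truth exactly.
#' Edge stages (3 and 17) have no sub-stage and are scored at stage
#' resolution.
#'
#' @param pred_stage,pred_substage Predicted annotation.
#' @param true_stage,true_substage Reference annotation.
#' @return 0/1 vector.
#' @export
score_substage <- function(pred_stage, pred_substage, true_stage,
                           true_substage) {
  same_stage <- pred_stage == true_stage
  edge <- true_stage %in% c(3L, 17L)
  same_sub <- !is.na(pred_substage) & !is.na(true_substage) &
    pred_substage == true_substage
  as.integer(same_stage & (edge | same_sub))
}

#' Stage accuracy indicator
#'
#' 1 when the predicted stage equals the true stage, whatever the
#' sub-stage.
#'
#' @inheritParams score_substage
#' @return 0/1 vector.
#' @export
score_stage <- function(pred_stage, pred_substage, true_stage,
                        true_substage) {
  as.integer(pred_stage == true_stage)
}

#' Plus-minus-sub-stage accuracy indicator
#'
#' 1 when the prediction is at most one half-stage from the truth on the
#' [half_stage_index()] axis (e.g. truth 7E accepts 6L, 7E and 7L).
#'
#' @inheritParams score_substage
#' @return 0/1 vector.
#' @export
score_pm_substage <- function(pred_stage, pred_substage, true_stage,
                              true_substage) {
  hp <- half_stage_index(pred_stage, pred_substage)
  ht <- half_stage_index(true_stage, true_substage)
  as.integer(abs(hp - ht) <= 1L)
}

#' Evaluate stage annotations against reference labels
#'
#' Computes the three accuracy criteria -- sub-stage accuracy (exact
#' stage + E/L), stage accuracy, and plus-minus-sub-stage accuracy (within
#' one half-stage) -- together with per-stage accuracy and the 15 x 15
#' confusion matrix over stages 3..17. The criteria are nested, so
#' `acc_substage <= acc_stage <= acc_pm_substage` always.
#'
#' @param pred Data.frame with columns `stage` and `substage` (as from
#'   [annotate_images()]).
#' @param truth Data.frame with columns `stage` and `substage`, aligned
#'   row-for-row with `pred`.
#' @return An `evaluation_report` list.
#' @export
evaluate_annotations <- function(pred, truth) {
  stopifnot(nrow(pred) == nrow(truth), nrow(pred) > 0L)
  s05 <- score_substage(pred$stage, pred$substage, truth$stage,
                        truth$substage)
  sst <- score_stage(pred$stage, pred$substage, truth$stage,
                     truth$substage)
  spm <- score_pm_substage(pred$stage, pred$substage, truth$stage,
                           truth$substage)
  confusion <- matrix(0L, length(STAGES), length(STAGES),
                      dimnames = list(truth = STAGES, predicted = STAGES))
  for (i in seq_len(nrow(pred))) {
    confusion[match(truth$stage[i], STAGES),
              match(pred$stage[i], STAGES)] <-
      confusion[match(truth$stage[i], STAGES),
                match(pred$stage[i], STAGES)] + 1L
  }
  per_stage <- vapply(STAGES, function(s) {
    idx <- truth$stage == s
    if (!any(idx)) NA_real_ else mean(sst[idx])
  }, numeric(1))
  names(per_stage) <- STAGES
  structure(list(acc_substage = mean(s05), acc_stage = mean(sst),
                 acc_pm_substage = mean(spm),
                 per_stage_accuracy = per_stage, confusion = confusion,
                 n = nrow(pred)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report, n = %d>\n", x$n))
  cat(sprintf("  sub-stage accuracy (exact stage + E/L): %.4f\n",
              x$acc_substage))
  cat(sprintf("  stage accuracy:                         %.4f\n",
              x$acc_stage))
  cat(sprintf("  plus-minus-sub-stage accuracy:          %.4f\n",
              x$acc_pm_substage))
  ps <- x$per_stage_accuracy[!is.na(x$per_stage_accuracy)]
  if (length(ps)) {
    cat("  per-stage accuracy:\n")
    print(round(ps, 3))
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' JSON summary plus the confusion matrix as CSV.
#'
#' @param report An `evaluation_report`.
#' @param path Output stem; writes `<path>.json` and
#'   `<path>_confusion.csv`.
#' @export
write_evaluation_report <- function(report, path) {
  jsonlite::write_json(
    list(n = report$n, acc_substage = report$acc_substage,
         acc_stage = report$acc_stage,
         acc_pm_substage = report$acc_pm_substage,
         per_stage_accuracy = as.list(report$per_stage_accuracy)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$confusion, paste0(path, "_confusion.csv"))
  invisible(path)
}

#' Held-out evaluation of the full annotation pipeline
#'
#' Splits the labelled data into a training and a held-out part
#' (stratified by stage), builds a classifier pool on the training part,
#' annotates the held-out part, and scores the three accuracy criteria.
#' With `folds > 1` the split is a k-fold partition and every fold is held
#' out once.
#'
#' @param X Feature matrix.
#' @param y Integer stage labels.
#' @param substage Optional reference sub-stage flags (`"E"`/`"L"`/`NA`);
#'   required for meaningful sub-stage accuracies on stages 4-16.
#' @param spec A [pool_spec()].
#' @param holdout Held-out fraction when `folds == 1` (default 0.2).
#' @param folds Number of cross-validation folds (1 = single holdout).
#' @param seed Seed for the evaluation split (the pool itself is seeded by
#'   `spec$master_seed`).
#' @param ... Passed to [build_pool()].
#' @return An `evaluation_report` (with the held-out `annotations`
#'   attached as an attribute).
#' @export
cross_validate <- function(X, y, substage = NULL, spec = pool_spec(),
                           holdout = 0.2, folds = 1L, seed = 1L, ...) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (is.null(substage)) substage <- rep(NA_character_, length(y))
  counts <- table(y)
  need <- if (folds > 1L) folds else 2L
  bad <- names(counts)[counts < need]
  if (length(bad)) {
    stop("too few samples for the requested split in stages: ",
         paste(bad, collapse = ", "))
  }
  fold_of <- integer(length(y))
  with_seed(seed, {
    if (folds > 1L) {
      for (cl in unique(y)) {
        idx <- which(y == cl)
        idx <- idx[sample.int(length(idx))]
        fold_of[idx] <- rep_len(seq_len(folds), length(idx))
      }
    } else {
      tr <- stratified_split(y, 1 - holdout)
      fold_of[] <- 1L
      fold_of[tr] <- 0L
    }
  })
  preds <- vector("list", max(fold_of))
  truths <- vector("list", max(fold_of))
  for (f in seq_len(max(fold_of))) {
    tr <- which(fold_of != f)
    te <- which(fold_of == f)
    pool <- build_pool(X[tr, , drop = FALSE], y[tr], spec, ...)
    ann <- annotate_images(pool, X[te, , drop = FALSE])
    preds[[f]] <- ann
    truths[[f]] <- data.frame(stage = y[te], substage = substage[te],
                              stringsAsFactors = FALSE)
  }
  pred <- do.call(rbind, preds)
  truth <- do.call(rbind, truths)
  report <- evaluate_annotations(pred, truth)
  attr(report, "annotations") <- pred
  report
}
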