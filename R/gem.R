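#' Build an expression map from a group of images
#'
#' Aggregates standardized expression images into a single composite:
#' intensities are inverted (staining is dark on a light background, so
#' signal becomes high), averaged pixelwise, and min-max rescaled to
#' `[0, 1]` so composites from groups of different sizes are
#' contrast-comparable.
#'
#' @param images Non-empty list of [embryo_image()] objects (or matrices)
#'   sharing one geometry.
#' @param group_label Identifier for the aggregated group (e.g. `"10E"`).
#' @return An `expression_map`: the composite matrix with attributes
#'   `group_label` and `n_images`.
#' @export
build_gem <- function(images, group_label = "") {
  if (length(images) == 0L) stop("cannot build an expression map from an empty group")
  dims <- dim(unclass(images[[1]]))
  acc <- matrix(0, dims[1], dims[2])
  for (im in images) {
    m <- unclass(im)
    if (!all(dim(m) == dims)) stop("images in a group must share dimensions")
    acc <- acc + (1 - m)
  }
  acc <- acc / length(images)
  rng <- range(acc)
  if (rng[2] > rng[1]) {
    acc <- (acc - rng[1]) / (rng[2] - rng[1])
  } else {
    acc[] <- 0
  }
  structure(acc, class = c("expression_map", "matrix", "array"),
            group_label = as.character(group_label),
            n_images = length(images))
}

#' @export
print.expression_map <- function(x, ...) {
  cat(sprintf("<expression_map '%s': %d x %d, %d images>\n",
              attr(x, "group_label"), nrow(x), ncol(x),
              attr(x, "n_images")))
  invisible(x)
}

#' Signal centroid column of an expression map
#'
#' Intensity-weighted mean column index: the position of the aggregate
#' expression signal along the anterior-posterior axis. Used to check
#' that successive stage composites progress monotonically.
#'
#' @param map An `expression_map` (or any nonnegative matrix).
#' @return Numeric column coordinate (1-based).
#' @export
map_centroid_col <- function(map) {
  m <- unclass(map)
  w <- colSums(m)
  if (sum(w) == 0) return(NA_real_)
  sum(seq_len(ncol(m)) * w) / sum(w)
}

#' Build an ordered series of expression maps
#'
#' Groups annotated images by developmental granularity and builds one
#' composite per group, in developmental order. Granularities: `"stage"`
#' (one map per stage), `"substage"` (stage x E/L; edge stages 3 and 17
#' form single groups), or `"score_bins"` (each stage's score interval
#' `[S - 0.5, S + 0.5)` divided into `bins` equal-width bins; images
#' without a score fall back to their stage group). Empty groups are
#' skipped.
#'
#' @param annotations Data.frame with columns `stage`, `substage`,
#'   `stage_score` (as from [annotate_images()]), aligned with `images`.
#' @param images List of [embryo_image()] objects.
#' @param granularity `"stage"`, `"substage"` or `"score_bins"`.
#' @param bins Bins per stage for `"score_bins"` (default 8).
#' @return Named list of `expression_map` objects in developmental order.
#' @export
build_gem_series <- function(annotations, images,
                             granularity = c("stage", "substage",
                                             "score_bins"),
                             bins = 8L) {
  granularity <- match.arg(granularity)
  stopifnot(nrow(annotations) == length(images))
  st <- annotations$stage
  key <- switch(granularity,
    stage = sprintf("%02d", st),
    substage = ifelse(is.na(annotations$substage),
                      sprintf("%02d", st),
                      sprintf("%02d%s", st, annotations$substage)),
    score_bins = {
      ss <- annotations$stage_score
      b <- ifelse(is.na(ss), NA_integer_,
                  pmin(pmax(floor((ss - (st - 0.5)) * bins) + 1L, 1L),
                       bins))
      ifelse(is.na(b), sprintf("%02d", st), sprintf("%02d.%02d", st, b))
    })
  labels <- sort(unique(key))
  maps <- lapply(labels, function(lb) {
    build_gem(images[key == lb], group_label = display_label(lb))
  })
  names(maps) <- vapply(labels, display_label, character(1))
  maps
}

# strip the zero padding used for lexicographic developmental ordering
display_label <- function(lb) sub("^0", "", lb)

#' Write a series of expression maps to disk
#'
#' One 8-bit PNG per map plus a manifest CSV (`group_label`, `n_images`,
#' `path`, `centroid_col`).
#'
#' @param maps Named list from [build_gem_series()].
#' @param dir Output directory (created if missing).
#' @return The manifest data.frame, invisibly.
#' @export
write_gem_series <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(
    group_label = vapply(maps, attr, character(1), "group_label"),
    n_images = vapply(maps, attr, integer(1), "n_images"),
    path = file.path(dir, sprintf("gem_%03d.png", seq_along(maps))),
    centroid_col = vapply(maps, map_centroid_col, numeric(1)),
    stringsAsFactors = FALSE)
  for (i in seq_along(maps)) {
    write_embryo_image(unclass(maps[[i]]), manifest$path[i])
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
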