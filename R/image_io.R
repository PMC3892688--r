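#' @useDynLib stagefly, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Standardized image geometry: all annotation operates on 128 x 320 grids
# (rows = dorsoventral axis, columns = anterior-posterior axis, anterior left).
STD_HEIGHT <- 128L
STD_WIDTH <- 320L

# Stage alphabet: embryogenesis stages 1-3 are morphologically indistinct in
# the imaging used here and are collapsed to a single label, 3.
STAGES <- 3:17

#' Construct an embryo image from a matrix of intensities
#'
#' An `embryo_image` is a plain numeric matrix (rows = image rows, top first)
#' with intensities in `[0, 1]` and an optional source identifier. It is the
#' unit of annotation throughout the package.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`.
#' @param source_id Optional string identifying the image origin.
#' @return An object of class `embryo_image`.
#' @export
embryo_image <- function(pixels, source_id = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix")
  }
  if (nrow(pixels) == 0L || ncol(pixels) == 0L) {
    stop("zero-area image")
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("image intensities must be finite")
  }
  if (min(pixels) < 0 || max(pixels) > 1) {
    stop("image intensities must lie in [0, 1]")
  }
  structure(pixels, class = c("embryo_image", "matrix", "array"),
            source_id = as.character(source_id))
}

#' @export
print.embryo_image <- function(x, ...) {
  cat(sprintf("<embryo_image %d x %d, source '%s', range [%.3f, %.3f]>\n",
              nrow(x), ncol(x), attr(x, "source_id"),
              min(x), max(x)))
  invisible(x)
}

#' Load and standardize an embryo image
#'
#' Reads a PNG, TIFF or JPEG file, converts color images to grayscale by
#' luminance weighting (0.299, 0.587, 0.114), rescales intensities to
#' `[0, 1]`, and (optionally) resamples to the standardized 128 x 320
#' geometry by bilinear interpolation.
#'
#' @param path Path to an image file.
#' @param enforce_size If `TRUE` (default), images whose dimensions differ
#'   from 128 x 320 are resampled to that size.
#' @return An [embryo_image()].
#' @export
load_embryo_image <- function(path, enforce_size = TRUE) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("unreadable image file '", path,
                                           "': ", conditionMessage(e)))
  dat <- EBImage::imageData(img)
  # EBImage indexes [x, y(, channel)]; collapse channels then transpose to
  # a rows-first matrix.
  if (length(dim(dat)) == 3L) {
    nch <- dim(dat)[3]
    if (nch >= 3L) {
      dat <- 0.299 * dat[, , 1] + 0.587 * dat[, , 2] + 0.114 * dat[, , 3]
    } else {
      dat <- dat[, , 1]
    }
  }
  if (length(dim(dat)) != 2L || any(dim(dat) == 0L)) stop("zero-area image")
  m <- t(dat)
  rng <- range(m)
  if (rng[1] < 0 || rng[2] > 1) {
    # 16-bit or unscaled payloads: map the observed range onto [0, 1]
    m <- (m - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  }
  if (enforce_size && (nrow(m) != STD_HEIGHT || ncol(m) != STD_WIDTH)) {
    r <- EBImage::resize(EBImage::Image(t(m)), w = STD_WIDTH, h = STD_HEIGHT)
    m <- t(EBImage::imageData(r))
    m <- pmin(pmax(m, 0), 1)
  }
  embryo_image(m, source_id = path)
}

#' Write an embryo image (or any [0,1] matrix) as an 8-bit PNG
#'
#' @param image Numeric matrix with values in `[0, 1]`.
#' @param path Output path.
#' @export
write_embryo_image <- function(image, path) {
  EBImage::writeImage(EBImage::Image(t(unclass(image))), path, type = "png",
                      bits.per.sample = 8L)
  invisible(path)
}

#' Read a stage-label table
#'
#' Parses a CSV with columns `image`, `stage` and optionally `substage`
#' (early/late flag, `E` or `L`, may be empty). Stage labels must lie in
#' 3..17 -- embryogenesis stages 1-3 are indistinguishable in this imagery
#' and must be encoded as stage 3. Sub-stage flags are only meaningful for
#' stages 4-16, whose neighbours on both sides exist.
#'
#' @param path Path to a CSV file with a header row.
#' @return A data.frame with columns `image` (character), `stage` (integer)
#'   and `substage` (character, `NA` when absent), plus any extra columns
#'   present in the file.
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) stop("label table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image", "stage") %in% names(df))) {
    stop("label table must have columns 'image' and 'stage'")
  }
  if (nrow(df) == 0L) {
    df$substage <- character(0)
    return(df[, unique(c("image", "stage", "substage", names(df)))])
  }
  stage <- suppressWarnings(as.integer(df$stage))
  bad <- which(is.na(stage) | !(stage %in% STAGES))
  if (length(bad)) {
    stop(sprintf(paste0("row %d: stage '%s' outside {3,...,17} ",
                        "(stages 1-3 must be encoded as 3)"),
                 bad[1], df$stage[bad[1]]))
  }
  df$stage <- stage
  if (is.null(df$substage)) df$substage <- NA_character_
  ss <- as.character(df$substage)
  ss[!is.na(ss) & ss == ""] <- NA_character_
  badss <- which(!is.na(ss) & !(ss %in% c("E", "L")))
  if (length(badss)) {
    stop(sprintf("row %d: substage '%s' must be E, L or empty",
                 badss[1], ss[badss[1]]))
  }
  edge <- which(!is.na(ss) & !(df$stage %in% 4:16))
  if (length(edge)) {
    stop(sprintf("row %d: substage given for edge stage %d (only stages 4-16 have sub-stages)",
                 edge[1], df$stage[edge[1]]))
  }
  df$substage <- ss
  df
}

#' Write a stage-label table
#'
#' @param df Data.frame with at least columns `image` and `stage`.
#' @param path Output CSV path.
#' @export
write_label_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
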