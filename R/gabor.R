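#' Log-Gabor transfer function
#'
#' Value of a log-Gabor filter at polar frequency coordinates. The filter is
#' Gaussian on a log radial-frequency axis and Gaussian in orientation:
#' \deqn{G(r, \theta) = \exp\!\left(-\frac{(\log(r/f_0))^2}{2(\log \sigma_{on f})^2}\right)
#'   \exp\!\left(-\frac{\Delta\theta^2}{2\sigma_\theta^2}\right)}
#' with \eqn{\Delta\theta} the wrapped angular distance to the filter
#' orientation. It has no DC component (the radial term vanishes as
#' \eqn{r \to 0}) and attains its maximum, 1, at \eqn{(r = f_0, \theta = \theta_0)}.
#'
#' @param r Radial frequency (cycles/pixel), strictly positive.
#' @param theta Angle (radians).
#' @param f0 Center frequency (cycles/pixel).
#' @param theta0 Filter orientation (radians).
#' @param sigma_on_f Ratio of the radial Gaussian width to `f0` (unitless).
#' @param theta_sigma Angular standard deviation (radians).
#' @return Filter gain in `[0, 1]` (vectorized over `r` and `theta`).
#' @export
log_gabor_transfer <- function(r, theta, f0, theta0, sigma_on_f, theta_sigma) {
  radial <- ifelse(r > 0,
                   exp(-(log(r / f0))^2 / (2 * log(sigma_on_f)^2)),
                   0)
  d <- theta - theta0
  d <- atan2(sin(d), cos(d)) # wrap to (-pi, pi]
  radial * exp(-d^2 / (2 * theta_sigma^2))
}

#' Build a log-Gabor filter bank
#'
#' Constructs `n_scales * n_orientations` frequency-domain transfer
#' functions over an `height x width` FFT grid. Scale `s` (1-based) has
#' center frequency `1 / (min_wavelength * scale_multiplier^(s-1))`
#' cycles/pixel; orientation `o` points at `(o-1) * pi / n_orientations`.
#' Each transfer function is single-sided in orientation, so the spatial
#' response is complex (in-phase and quadrature pair) and its modulus is
#' the local texture energy. The DC bin is identically zero.
#'
#' The defaults (4 scales starting at wavelength 3 px with multiplier 2.1,
#' 6 orientations, `sigma_on_f = 0.55`, angular sigma 0.66 of the
#' orientation spacing) give roughly two-octave radial bandwidth and evenly
#' overlapping orientation tuning -- the standard general-purpose texture
#' bank.
#'
#' @param height,width Grid dimensions in pixels.
#' @param n_scales,n_orientations Bank size (default 4 x 6 = 24 filters).
#' @param min_wavelength Shortest wavelength in pixels (must be >= 2,
#'   the Nyquist limit).
#' @param scale_multiplier Wavelength ratio between successive scales.
#' @param sigma_on_f Radial bandwidth parameter (sigma/f0 ratio).
#' @param theta_sigma_ratio Angular sigma as a fraction of the orientation
#'   spacing `pi / n_orientations`.
#' @return An object of class `log_gabor_bank`: a list with the parameters
#'   and `transfer`, a list of real-valued `height x width` matrices in FFT
#'   layout (DC at element `[1, 1]`), ordered scale-major then orientation.
#' @export
log_gabor_bank <- function(height = 128L, width = 320L,
                           n_scales = 4L, n_orientations = 6L,
                           min_wavelength = 3, scale_multiplier = 2.1,
                           sigma_on_f = 0.55, theta_sigma_ratio = 0.66) {
  stopifnot(n_scales >= 1L, n_orientations >= 1L, height >= 2L, width >= 2L)
  if (min_wavelength < 2) {
    stop("min_wavelength must be >= 2 pixels (Nyquist limit)")
  }
  # FFT-layout normalized frequency axes in cycles/pixel
  fy <- fft_freqs(height)
  fx <- fft_freqs(width)
  r <- sqrt(outer(fy^2, fx^2, `+`))
  theta <- atan2(outer(fy, rep(1, width)), outer(rep(1, height), fx))
  theta_sigma <- theta_sigma_ratio * pi / n_orientations
  f0s <- 1 / (min_wavelength * scale_multiplier^(seq_len(n_scales) - 1))
  transfer <- vector("list", n_scales * n_orientations)
  k <- 0L
  for (s in seq_len(n_scales)) {
    for (o in seq_len(n_orientations)) {
      theta0 <- (o - 1) * pi / n_orientations
      H <- log_gabor_transfer(r, theta, f0s[s], theta0, sigma_on_f,
                              theta_sigma)
      H[1, 1] <- 0 # no DC component
      k <- k + 1L
      transfer[[k]] <- H
    }
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_scales = as.integer(n_scales),
                 n_orientations = as.integer(n_orientations),
                 center_frequencies = f0s, sigma_on_f = sigma_on_f,
                 theta_sigma = theta_sigma,
                 min_wavelength = min_wavelength,
                 scale_multiplier = scale_multiplier,
                 transfer = transfer),
            class = "log_gabor_bank")
}

# FFT bin frequencies in cycles per pixel (DC first, negative half wrapped)
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

#' @export
print.log_gabor_bank <- function(x, ...) {
  cat(sprintf("<log_gabor_bank %d x %d: %d scales x %d orientations = %d filters>\n",
              x$height, x$width, x$n_scales, x$n_orientations,
              length(x$transfer)))
  cat("  center frequencies (cycles/px):",
      paste(signif(x$center_frequencies, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Filter an image with a log-Gabor bank
#'
#' Filters in the frequency domain: each output is the pixelwise modulus of
#' the inverse FFT of (image spectrum x transfer function). Because the
#' filters are single-sided, the modulus is the local energy envelope of
#' the oriented band-pass response.
#'
#' @param image An [embryo_image()] or numeric matrix matching the bank
#'   dimensions.
#' @param bank A [log_gabor_bank()].
#' @return A list of nonnegative magnitude matrices, one per filter, in the
#'   bank's scale-major order; each carries attributes `scale_index` and
#'   `orientation_index` (0-based).
#' @export
apply_filter_bank <- function(image, bank) {
  m <- unclass(image)
  if (nrow(m) != bank$height || ncol(m) != bank$width) {
    stop(sprintf("image is %d x %d but bank was built for %d x %d",
                 nrow(m), ncol(m), bank$height, bank$width))
  }
  spec <- stats::fft(m)
  npix <- length(m)
  out <- vector("list", length(bank$transfer))
  for (k in seq_along(bank$transfer)) {
    resp <- stats::fft(spec * bank$transfer[[k]], inverse = TRUE) / npix
    g <- Mod(resp)
    attr(g, "scale_index") <- (k - 1L) %/% bank$n_orientations
    attr(g, "orientation_index") <- (k - 1L) %% bank$n_orientations
    out[[k]] <- g
  }
  out
}

#' Block-mean down-sampling
#'
#' Partitions a matrix into non-overlapping `block x block` tiles and
#' returns the tile means in row-major order (tiles of the first block-row
#' first, left to right).
#'
#' @param x Numeric matrix whose dimensions are divisible by `block`.
#' @param block Tile side in pixels (default 8, giving 16 x 40 = 640 tiles
#'   on a 128 x 320 image).
#' @return Numeric vector of `(nrow/block) * (ncol/block)` tile means.
#' @export
block_mean <- function(x, block = 8L) {
  x <- unclass(x)
  h <- nrow(x); w <- ncol(x)
  if (h %% block != 0L || w %% block != 0L) {
    stop(sprintf("dimensions %d x %d not divisible by block size %d",
                 h, w, block))
  }
  bh <- h %/% block; bw <- w %/% block
  rs <- rowsum(x, group = rep(seq_len(bh), each = block))
  cs <- rowsum(t(rs), group = rep(seq_len(bw), each = block))
  # cs is bw x bh = transposed block grid; its column-major vector is the
  # row-major traversal of the block grid
  as.vector(cs) / (block * block)
}

#' Group structure of block-mean Gabor features
#'
#' Each image region (sub-block) contributes one feature per Gabor image,
#' so the feature vector partitions naturally into one group per region:
#' group `g` holds feature indices `(k-1)*n_blocks + g` for every filter
#' `k`. This is the structure used by the group and sparse-group Lasso
#' penalties to select whole image regions.
#'
#' @param n_filters Number of Gabor images (default 24).
#' @param n_blocks Number of regions per Gabor image (default 640).
#' @return A list of `n_blocks` integer vectors, each of length
#'   `n_filters`, forming a disjoint partition of `1:(n_filters*n_blocks)`.
#' @export
gabor_group_structure <- function(n_filters = 24L, n_blocks = 640L) {
  lapply(seq_len(n_blocks), function(g) {
    as.integer((seq_len(n_filters) - 1L) * n_blocks + g)
  })
}

#' Extract the block-mean log-Gabor feature vector of an image
#'
#' Applies the filter bank, down-samples each of the Gabor magnitude images
#' by [block_mean()], and concatenates them: feature index
#' `(k-1)*n_blocks + b` holds region `b` of Gabor image `k` (filters in
#' scale-major order, regions in row-major order). For the standard
#' 128 x 320 geometry with the default 24-filter bank and 8 x 8 blocks the
#' vector has 24 x 640 = 15360 entries.
#'
#' @param image An [embryo_image()] or matching numeric matrix.
#' @param bank A [log_gabor_bank()].
#' @param block Block side in pixels (default 8).
#' @return A list with `values` (the feature vector) and `groups` (the
#'   region [gabor_group_structure()]).
#' @export
extract_features <- function(image, bank, block = 8L) {
  gims <- apply_filter_bank(image, bank)
  feats <- vapply(gims, block_mean, numeric((bank$height %/% block) *
                                              (bank$width %/% block)),
                  block = block)
  n_blocks <- nrow(feats)
  list(values = as.vector(feats),
       groups = gabor_group_structure(length(gims), n_blocks))
}

#' Featurize a list of images into a feature matrix
#'
#' @param images List of [embryo_image()] objects (or matrices).
#' @param bank A [log_gabor_bank()]; built to the standard geometry if
#'   omitted.
#' @param block Block side in pixels.
#' @return A list with `X` (n_images x n_features matrix, one row per
#'   image, row names from image source ids when available), `groups`, and
#'   `bank`.
#' @export
featurize_images <- function(images, bank = NULL, block = 8L) {
  if (length(images) == 0L) stop("no images to featurize")
  if (is.null(bank)) {
    bank <- log_gabor_bank(height = nrow(images[[1]]),
                           width = ncol(images[[1]]))
  }
  rows <- lapply(images, function(im) extract_features(im, bank, block))
  X <- do.call(rbind, lapply(rows, `[[`, "values"))
  ids <- vapply(images, function(im) {
    sid <- attr(im, "source_id"); if (is.null(sid)) "" else sid
  }, character(1))
  if (any(nzchar(ids))) rownames(X) <- ids
  list(X = X, groups = rows[[1]]$groups, bank = bank)
}

#' Persist a feature matrix as a binary container with a JSON sidecar
#'
#' The container holds two little-endian int32 dimensions followed by the
#' row-major float64 payload; the sidecar (`<path>.json`) records the bank
#' parameters and the feature-ordering contract.
#'
#' @param feats Result of [featurize_images()].
#' @param path Output path for the binary container.
#' @export
write_feature_matrix <- function(feats, path) {
  X <- feats$X
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(dim(X)), con, size = 4L, endian = "little")
  writeBin(as.vector(t(X)), con, size = 8L, endian = "little")
  bank <- feats$bank
  meta <- list(
    n_rows = nrow(X), n_cols = ncol(X),
    ordering = "feature index = (filter_index-1)*n_blocks + block_index; filters scale-major, blocks row-major",
    bank = bank[c("height", "width", "n_scales", "n_orientations",
                  "min_wavelength", "scale_multiplier", "sigma_on_f",
                  "theta_sigma")],
    image_ids = if (is.null(rownames(X))) list() else rownames(X))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a persisted feature matrix
#'
#' Reads the binary container written by [write_feature_matrix()].
#'
#' @param path Path to the binary container.
#' @return A numeric matrix (row names restored from the sidecar if
#'   present).
#' @export
read_feature_matrix <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  d <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  X <- matrix(readBin(con, "double", n = prod(d), size = 8L,
                      endian = "little"),
              nrow = d[1], ncol = d[2], byrow = TRUE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (length(meta$image_ids)) rownames(X) <- unlist(meta$image_ids)
  }
  X
}
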