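#' Specification of a synthetic embryo-image corpus
#'
#' The generator emulates the standardized expression-image corpus the
#' annotation system is designed for: 128 x 320 grayscale images of a
#' laterally viewed embryo whose appearance changes monotonically with a
#' latent developmental time `t` in `[0, 1]`. Each of the requested stages
#' occupies an equal sub-interval of `[0, 1]`; an image's stage (and E/L
#' sub-stage, by the half of the sub-interval its `t` falls in) is known
#' by construction, so the full pipeline can be validated end to end.
#'
#' Two appearance channels carry the developmental signal so that both the
#' texture-sensitive Gabor scales and the region-selecting group penalties
#' are exercised: (i) a striped texture field whose dominant spatial
#' frequency interpolates across `texture_freq_range` with `t`, and (ii) a
#' dark expression band whose anterior-posterior position interpolates
#' from `band_start` to `band_end` (fractions of the image width) with
#' `t`. Pixel noise is Gaussian with `noise_sd`, clipped to `[0, 1]`.
#'
#' @param n_per_stage Images per stage (>= 1).
#' @param stages Subset of 3..17 (default all 15).
#' @param noise_sd Gaussian pixel-noise standard deviation (intensity
#'   units; default 0.05).
#' @param seed Integer seed; the corpus is fully reproducible from it.
#' @param band_start,band_end Fractional anterior-posterior positions of
#'   the expression band at `t = 0` and `t = 1`.
#' @param texture_freq_range Dominant texture frequency at `t = 0` and
#'   `t = 1` (cycles/pixel).
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_stage = 40L, stages = 3:17,
                           noise_sd = 0.05, seed = 1L,
                           band_start = 0.25, band_end = 0.75,
                           texture_freq_range = c(0.04, 0.18)) {
  if (n_per_stage < 1L) stop("n_per_stage must be >= 1")
  stages <- sort(unique(as.integer(stages)))
  if (!all(stages %in% STAGES)) {
    stop("stages must be a subset of 3..17")
  }
  stopifnot(noise_sd >= 0, length(texture_freq_range) == 2L)
  structure(list(n_per_stage = as.integer(n_per_stage), stages = stages,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 band_start = band_start, band_end = band_end,
                 texture_freq_range = texture_freq_range),
            class = "synthetic_spec")
}

# deterministic render of one embryo at latent time t (no noise)
render_embryo <- function(t, spec, height = 128L, width = 320L) {
  cy <- (height + 1) / 2; cx <- (width + 1) / 2
  ry <- 0.42 * height; rx <- 0.47 * width
  row <- matrix(seq_len(height), height, width)
  col <- matrix(seq_len(width), height, width, byrow = TRUE)
  mask <- ((row - cy) / ry)^2 + ((col - cx) / rx)^2 <= 1
  img <- matrix(1, height, width) # white background
  base <- 0.9
  # striped texture, frequency sliding with t; mean-centred over the mask
  # so the texture adds no net optical mass
  f <- spec$texture_freq_range[1] +
    t * diff(spec$texture_freq_range)
  tex <- cos(2 * pi * f * (row - cy))
  tex <- tex - mean(tex[mask])
  # expression band, dark, moving along the anterior-posterior axis
  bandc <- (spec$band_start + t * (spec$band_end - spec$band_start)) * width
  band <- 0.5 * exp(-((col - bandc)^2) / (2 * 14^2))
  inside <- base + 0.07 * tex - band
  img[mask] <- inside[mask]
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic labelled corpus
#'
#' Draws each image's latent time uniformly within its stage's
#' sub-interval of `[0, 1]`, renders the embryo, and adds clipped Gaussian
#' noise. Fully reproducible from `spec$seed` (the caller's RNG stream is
#' left untouched).
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `images` (list of [embryo_image()]) and `labels`, a
#'   data.frame with columns `image` (generated id), `stage`, `substage`
#'   (`E`/`L` for stages 4-16, `NA` at the edges), `t` (latent time) and
#'   `substage_truth` (the E/L half of the stage interval, kept for all
#'   stages).
#' @export
generate_corpus <- function(spec = synthetic_spec()) {
  K <- length(spec$stages)
  n <- spec$n_per_stage * K
  images <- vector("list", n)
  stage <- integer(n); tval <- numeric(n)
  with_seed(spec$seed, {
    i <- 0L
    for (k in seq_len(K)) {
      lo <- (k - 1) / K; hi <- k / K
      for (j in seq_len(spec$n_per_stage)) {
        i <- i + 1L
        stage[i] <- spec$stages[k]
        tval[i] <- stats::runif(1, lo, hi)
      }
    }
    for (i in seq_len(n)) {
      m <- render_embryo(tval[i], spec)
      if (spec$noise_sd > 0) {
        m <- m + matrix(stats::rnorm(length(m), sd = spec$noise_sd),
                        nrow(m), ncol(m))
        m <- pmin(pmax(m, 0), 1)
      }
      images[[i]] <- embryo_image(m, source_id = sprintf("synthetic_%04d", i))
    }
  })
  k_of <- match(stage, spec$stages)
  mid <- ((k_of - 0.5) / K)
  truth_sub <- ifelse(tval < mid, "E", "L")
  labels <- data.frame(
    image = sprintf("synthetic_%04d", seq_len(n)),
    stage = stage,
    substage = ifelse(stage %in% 4:16, truth_sub, NA_character_),
    t = tval,
    substage_truth = truth_sub,
    stringsAsFactors = FALSE)
  list(images = images, labels = labels, spec = spec)
}

#' Write a synthetic corpus to disk
#'
#' PNG images plus a `labels.csv` in the standard label-table schema
#' (`image`, `stage`, `substage`) with the extra ground-truth columns `t`
#' and `substage_truth`.
#'
#' @param corpus Result of [generate_corpus()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- corpus$labels
  labels$image <- paste0(labels$image, ".png")
  for (i in seq_along(corpus$images)) {
    write_embryo_image(corpus$images[[i]], file.path(dir, labels$image[i]))
  }
  write_label_table(labels, file.path(dir, "labels.csv"))
  invisible(dir)
}
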