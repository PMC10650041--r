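# Seeded generator of small-target segmentation scenes.
#
# The regime being emulated: a foreground that occupies well under 1% of the
# image, at modest contrast, sitting on a textured background with bright
# non-target distractors, and (for volumes) only a small fraction of slices
# containing any foreground at all.

#' Scene configuration for the synthetic small-target generator
#'
#' Defaults encode the difficulty regime the network targets: elliptical
#' foreground targets covering at most 1% of the pixels, a background made of
#' smoothed Gaussian noise plus a sinusoidal texture, bright Gaussian-bump
#' distractors that defeat naive intensity thresholding, and volumes in which
#' only ~5% of slices are positive.
#'
#' @param image_size side length in pixels (images are square).
#' @param n_targets integer range `c(min, max)` of targets per positive image.
#' @param target_radius range of ellipse semi-axes in pixels (>= 1).
#' @param max_foreground_fraction hard upper bound on mask foreground
#'   fraction, in (0, 0.5).
#' @param contrast additive intensity offset of targets over the local
#'   background (images live in \[0, 1\]).
#' @param noise_scale standard deviation of the smoothed background noise.
#' @param noise_smoothing Gaussian blur sigma (px) applied to the noise.
#' @param texture_amplitude amplitude of the sinusoidal background texture.
#' @param n_distractors integer range of bright non-target blobs per image.
#' @param positive_slice_fraction fraction of volume slices containing
#'   foreground.
#' @param seed integer seed fixing the full sample stream.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(image_size = 128L,
                         n_targets = c(1L, 3L),
                         target_radius = c(2, 5),
                         max_foreground_fraction = 0.01,
                         contrast = 0.35,
                         noise_scale = 0.10,
                         noise_smoothing = 3,
                         texture_amplitude = 0.10,
                         n_distractors = c(2L, 6L),
                         positive_slice_fraction = 0.05,
                         seed = 1L) {
  if (max_foreground_fraction <= 0 || max_foreground_fraction >= 0.5)
    stop("max_foreground_fraction must lie in (0, 0.5)")
  if (min(target_radius) < 1) stop("target radii must be >= 1 px")
  if (positive_slice_fraction < 0 || positive_slice_fraction > 1)
    stop("positive_slice_fraction must lie in [0, 1]")
  structure(list(image_size = as.integer(image_size),
                 n_targets = as.integer(range(n_targets)),
                 target_radius = as.numeric(range(target_radius)),
                 max_foreground_fraction = max_foreground_fraction,
                 contrast = contrast,
                 noise_scale = noise_scale,
                 noise_smoothing = noise_smoothing,
                 texture_amplitude = texture_amplitude,
                 n_distractors = as.integer(range(n_distractors)),
                 positive_slice_fraction = positive_slice_fraction,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# separable Gaussian blur with edge replication
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n1 <- nrow(img); n2 <- ncol(img)
  pad_idx <- function(n) pmin(pmax(seq(1 - r, n + r), 1L), n)
  p <- img[pad_idx(n1), pad_idx(n2)]
  x4 <- array(p, c(dim(p), 1L, 1L))
  kern <- array(outer(k, k), c(2L * r + 1L, 2L * r + 1L, 1L, 1L))
  out <- cpp_conv2d_fwd(x4, kern, NULL, 1L, 0L, 1L, 0L)
  matrix(out, n1, n2)
}

draw_ellipse <- function(size, center, ax_a, ax_b, theta) {
  gr <- matrix(seq_len(size), size, size)          # rows
  gc <- matrix(seq_len(size), size, size, byrow = TRUE)
  dr <- gr - center[1]; dc <- gc - center[2]
  u <- cos(theta) * dr + sin(theta) * dc
  v <- -sin(theta) * dr + cos(theta) * dc
  (u / ax_a)^2 + (v / ax_b)^2 <= 1
}

gaussian_bump <- function(size, center, sigma, amp) {
  gr <- matrix(seq_len(size), size, size)
  gc <- matrix(seq_len(size), size, size, byrow = TRUE)
  amp * exp(-((gr - center[1])^2 + (gc - center[2])^2) / (2 * sigma^2))
}

sample_int_range <- function(rng) if (rng[1] >= rng[2]) rng[1] else
  rng[1] + floor(runif(1) * (rng[2] - rng[1] + 1))

generate_sample_impl <- function(config, force_empty = FALSE) {
  s <- config$image_size
  # background: base level + smoothed noise + sinusoidal texture
  noise <- gauss_blur(matrix(rnorm(s * s), s, s), config$noise_smoothing)
  bg <- 0.35 + noise / stats::sd(noise) * config$noise_scale
  freq <- runif(1, 1 / 32, 1 / 8)
  ang <- runif(1, 0, pi)
  phase <- runif(1, 0, 2 * pi)
  gr <- matrix(seq_len(s), s, s)
  gc <- matrix(seq_len(s), s, s, byrow = TRUE)
  bg <- bg + config$texture_amplitude *
    sin(2 * pi * freq * (cos(ang) * gr + sin(ang) * gc) + phase)

  # bright non-target distractors
  nd <- sample_int_range(config$n_distractors)
  for (i in seq_len(nd)) {
    bg <- bg + gaussian_bump(s, runif(2, 4, s - 3), runif(1, 1, 3),
                             runif(1, 0.35, 0.55))
  }

  # elliptical targets under the foreground budget
  mask <- matrix(0, s, s)
  if (!force_empty && config$n_targets[2] > 0) {
    max_px <- config$max_foreground_fraction * s * s
    for (attempt in seq_len(25L)) {
      nt <- sample_int_range(config$n_targets)
      m <- matrix(FALSE, s, s)
      for (i in seq_len(nt)) {
        ax <- runif(2, config$target_radius[1], config$target_radius[2])
        margin <- ceiling(max(ax)) + 1
        ctr <- runif(2, margin, s - margin)
        m <- m | draw_ellipse(s, ctr, ax[1], ax[2], runif(1, 0, pi))
      }
      if (sum(m) <= max_px && (nt == 0 || sum(m) > 0)) {
        mask <- m * 1
        break
      }
      if (attempt == 25L)
        stop("generate_sample: could not satisfy the foreground-fraction bound ",
             "(radius range too large for max_foreground_fraction = ",
             config$max_foreground_fraction, ")")
    }
  }
  img <- bg + config$contrast * mask
  img <- gauss_blur(img, 0.6)  # soften target edges slightly
  img[img < 0] <- 0; img[img > 1] <- 1
  list(image = img, mask = mask, spacing = c(1, 1))
}

#' Generate one synthetic small-target sample
#'
#' @param config a [scene_config()].
#' @param seed optional integer overriding `config$seed` for this sample.
#' @return a `sample_pair`: list with `image` (matrix in \[0, 1\]), `mask`
#'   (0/1 matrix, foreground fraction at most
#'   `config$max_foreground_fraction`) and `spacing` (mm).
#' @examples
#' sp <- generate_sample(scene_config(image_size = 64, seed = 7))
#' mean(sp$mask) <= 0.01
#' @export
generate_sample <- function(config, seed = config$seed) {
  out <- with_seed(seed, generate_sample_impl(config))
  structure(out, class = "sample_pair")
}

#' Generate a sparse-positive volume as an ordered list of slices
#'
#' Emulates volumetric data in which only a small fraction of slices contains
#' any foreground: `round(positive_slice_fraction * n_slices)` slices get
#' targets, the rest are background-only.
#'
#' @param config a [scene_config()].
#' @param n_slices number of slices (>= 20).
#' @return list of `sample_pair`s with attribute `positive_slices` (indices).
#' @export
generate_volume <- function(config, n_slices = 100L) {
  if (n_slices < 20L) stop("generate_volume: need at least 20 slices")
  with_seed(config$seed, {
    n_pos <- round(config$positive_slice_fraction * n_slices)
    pos <- if (n_pos > 0) sort(sample(n_slices, n_pos)) else integer(0)
    slices <- lapply(seq_len(n_slices), function(i)
      structure(generate_sample_impl(config, force_empty = !(i %in% pos)),
                class = "sample_pair"))
    structure(slices, positive_slices = pos)
  })
}

#' Generate a dataset on disk
#'
#' Writes paired 8-bit grayscale TIFF images and masks plus a CSV manifest
#' listing paths, per-sample seeds and foreground fractions.
#'
#' @param config a [scene_config()].
#' @param n_samples number of samples to emit.
#' @param out_dir writable output directory (created if needed).
#' @return the manifest as a data.frame, invisibly; also written to
#'   `manifest.csv`.
#' @export
generate_dataset <- function(config, n_samples, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("generate_dataset: cannot create ", out_dir)
  rows <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    seed_i <- config$seed + i - 1L
    sp <- generate_sample(config, seed = seed_i)
    img_path <- file.path(out_dir, sprintf("image_%04d.tif", i))
    mask_path <- file.path(out_dir, sprintf("mask_%04d.tif", i))
    tiff_write(sp$image, img_path)
    tiff_write(sp$mask, mask_path)
    rows[[i]] <- data.frame(image = basename(img_path), mask = basename(mask_path),
                            seed = seed_i, foreground_fraction = mean(sp$mask),
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [generate_dataset()]
#'
#' @param dir directory containing `manifest.csv` (or paired
#'   `image_*.tif` / `mask_*.tif` files).
#' @return list of `sample_pair`s.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (file.exists(mf)) {
    manifest <- read.csv(mf, stringsAsFactors = FALSE)
    imgs <- file.path(dir, manifest$image)
    masks <- file.path(dir, manifest$mask)
  } else {
    imgs <- sort(Sys.glob(file.path(dir, "image_*.tif")))
    masks <- sort(Sys.glob(file.path(dir, "mask_*.tif")))
    if (length(imgs) == 0 || length(imgs) != length(masks))
      stop("read_dataset: no manifest.csv and no matching image_/mask_ TIFF pairs in ", dir)
  }
  lapply(seq_along(imgs), function(i) {
    structure(list(image = tiff_read(imgs[i]),
                   mask = 1 * (tiff_read(masks[i]) > 0.5),
                   spacing = c(1, 1)),
              class = "sample_pair")
  })
}
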