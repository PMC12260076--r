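# Synthetic paired mask-image datasets.
#
# Every module of the package is exercisable without downloads: masks with
# known structure (lesion-like blobs, annular rings, branching vessel trees)
# are rasterized, and the image is a deterministic function of the mask, a
# smooth texture field and a noise draw.  Coordinates are row-major and
# 0-based in the documentation: pixel (r, c) = (row from top, column from
# left); internally R's 1-based column-major matrices are used.

#' A paired image and label mask
#'
#' @param image Numeric `H x W` matrix (or `H x W x C` array), values in
#'   `[-1, 1]`.
#' @param mask Integer `H x W` matrix with values in `{0..label_count-1}`.
#' @param id Opaque identifier string.
#' @param label_count Number of labels `L`.
#' @return A `mask_image_pair` object.
#' @export
mask_image_pair <- function(image, mask, id = "pair", label_count = 2L) {
  dimg <- dim(image)[1:2]
  if (!identical(as.integer(dimg), as.integer(dim(mask)))) {
    stop("image and mask spatial dimensions differ")
  }
  if (any(mask < 0 | mask >= label_count)) {
    stop("mask contains labels outside {0..", label_count - 1L, "}")
  }
  if (any(image < -1 - 1e-12 | image > 1 + 1e-12)) {
    stop("image values must lie in [-1, 1]")
  }
  structure(list(image = image, mask = matrix(as.integer(mask), nrow(mask)),
                 id = as.character(id), label_count = as.integer(label_count)),
            class = "mask_image_pair")
}

#' @export
print.mask_image_pair <- function(x, ...) {
  cat("<mask_image_pair '", x$id, "' ", nrow(x$mask), "x", ncol(x$mask),
      ", ", sum(x$mask > 0), " fg px>\n", sep = "")
  invisible(x)
}

#' A split collection of mask-image pairs
#'
#' @param pairs List of [mask_image_pair()] objects sharing dimensions and
#'   label count.
#' @param split One of `"train"`, `"validation"`, `"test"`.
#' @param label_count Number of labels.
#' @param provenance Record of generator parameters or manifest path.
#' @return A `seg_dataset` object.
#' @export
seg_dataset <- function(pairs, split = c("train", "validation", "test"),
                        label_count = 2L, provenance = list()) {
  split <- match.arg(split)
  if (length(pairs) > 0L) {
    d0 <- dim(pairs[[1L]]$mask)
    for (p in pairs) {
      stopifnot(inherits(p, "mask_image_pair"), identical(dim(p$mask), d0))
    }
  }
  structure(list(pairs = pairs, split = split,
                 label_count = as.integer(label_count),
                 provenance = provenance),
            class = "seg_dataset")
}

#' @export
print.seg_dataset <- function(x, ...) {
  sz <- if (length(x$pairs)) paste(dim(x$pairs[[1L]]$mask), collapse = "x") else "?"
  cat("<seg_dataset: ", length(x$pairs), " ", x$split, " pairs, ", sz,
      ", L=", x$label_count, ">\n", sep = "")
  invisible(x)
}

#' @export
length.seg_dataset <- function(x) length(x$pairs)

ds_masks <- function(ds) lapply(ds$pairs, `[[`, "mask")
ds_images <- function(ds) lapply(ds$pairs, `[[`, "image")

#' Configuration for a synthetic shape dataset
#'
#' Defaults emulate an ultra-low-data medical segmentation task at desk
#' scale: few pairs, small images, moderate foreground/background contrast,
#' a smooth nuisance texture, and additive noise.
#'
#' @param n Number of pairs (>= 0).
#' @param image_size Pixels per side (>= 16).
#' @param shape_kind `"blob"` (union of random ellipses), `"ring"`
#'   (annulus), or `"vessel"` (random branching tree).
#' @param contrast Foreground minus background mean intensity, in `[0, 2]`.
#' @param noise_sd Additive Gaussian noise standard deviation (>= 0).
#' @param texture List with `amplitude` (intensity units) and `scale`
#'   (smoothing length in pixels) of the nuisance texture field.
#' @param ood_shift Optional appearance-shift record, see
#'   [make_ood_variant()].
#' @param seed Integer seed; identical config + seed gives an identical
#'   dataset.
#' @param split Dataset split tag.
#' @return A `shape_dataset_config` list.
#' @export
shape_dataset_config <- function(n, image_size = 32L,
                                 shape_kind = c("blob", "ring", "vessel"),
                                 contrast = 0.5, noise_sd = 0.3,
                                 texture = list(amplitude = 0.25, scale = 4),
                                 ood_shift = NULL, seed = 1L,
                                 split = "train") {
  shape_kind <- match.arg(shape_kind)
  if (n < 0L) stop("n must be non-negative")
  if (image_size < 16L) stop("image_size must be at least 16")
  if (contrast < 0 || contrast > 2) stop("contrast must lie in [0, 2]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(n = as.integer(n), image_size = as.integer(image_size),
                 shape_kind = shape_kind, contrast = contrast,
                 noise_sd = noise_sd, texture = texture,
                 ood_shift = ood_shift, seed = as.integer(seed),
                 split = split),
            class = "shape_dataset_config")
}

## ---- mask rasterizers -----------------------------------------------------

raster_grid <- function(size) {
  r <- matrix(seq_len(size), size, size)           # row index
  c <- matrix(seq_len(size), size, size, byrow = TRUE)
  list(r = r, c = c)
}

draw_ellipse <- function(g, size, cy, cx, ay, ax, theta) {
  dy <- g$r - cy; dx <- g$c - cx
  u <- cos(theta) * dy + sin(theta) * dx
  v <- -sin(theta) * dy + cos(theta) * dx
  (u / ay)^2 + (v / ax)^2 <= 1
}

mask_blob <- function(size, g) {
  m <- matrix(FALSE, size, size)
  for (i in seq_len(sample(1:3, 1))) {
    m <- m | draw_ellipse(g, size,
                          cy = stats::runif(1, 0.3, 0.7) * size,
                          cx = stats::runif(1, 0.3, 0.7) * size,
                          ay = stats::runif(1, 0.10, 0.25) * size,
                          ax = stats::runif(1, 0.10, 0.25) * size,
                          theta = stats::runif(1, 0, pi))
  }
  m
}

mask_ring <- function(size, g) {
  cy <- stats::runif(1, 0.4, 0.6) * size
  cx <- stats::runif(1, 0.4, 0.6) * size
  ro <- stats::runif(1, 0.22, 0.38) * size
  ri <- ro * stats::runif(1, 0.4, 0.7)
  d <- sqrt((g$r - cy)^2 + (g$c - cx)^2)
  d <= ro & d > ri
}

mask_vessel <- function(size, g) {
  m <- matrix(FALSE, size, size)
  stamp <- function(y, x, w) {
    m <<- m | ((g$r - y)^2 + (g$c - x)^2 <= w^2)
  }
  grow <- function(y, x, angle, len, w, depth) {
    steps <- max(2L, ceiling(len))
    for (s in seq_len(steps)) {
      yy <- y + sin(angle) * (len * s / steps)
      xx <- x + cos(angle) * (len * s / steps)
      stamp(yy, xx, w)
    }
    y2 <- y + sin(angle) * len
    x2 <- x + cos(angle) * len
    if (depth > 0L) {
      nb <- sample(1:2, 1)
      for (b in seq_len(nb)) {
        grow(y2, x2, angle + stats::runif(1, -0.9, 0.9),
             len * stats::runif(1, 0.55, 0.8), max(w * 0.8, 0.7), depth - 1L)
      }
    }
  }
  grow(y = size * stats::runif(1, 0.75, 0.95),
       x = size * stats::runif(1, 0.3, 0.7),
       angle = -pi / 2 + stats::runif(1, -0.5, 0.5),
       len = size * stats::runif(1, 0.25, 0.4),
       w = max(1, size / 28), depth = 2L)
  m
}

# smooth zero-mean unit-sd random field: white noise blurred by a separable
# Gaussian (banded-matrix convolution)
smooth_field <- function(size, scale) {
  z <- matrix(stats::rnorm(size * size), size, size)
  if (scale <= 0) return(z)
  K <- gauss_band(size, scale)
  f <- K %*% z %*% t(K)
  f <- f - mean(f)
  s <- stats::sd(as.vector(f))
  if (s > 0) f / s else f
}

gauss_band <- function(size, sigma) {
  key <- paste("gb", size, signif(sigma, 8), sep = "_")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- seq_len(size)
  K <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
  K <- K / rowSums(K)
  .nn_cache[[key]] <- K
  K
}

# Compose an image from a mask: intensity levels -contrast/2 (background)
# and +contrast/2 (foreground), plus a per-region mean-centred smooth
# texture and additive noise.  The texture field is clamped to +-2.5
# standard deviations and its amplitude capped by the remaining headroom,
# so the noise-free image never clips and (mean fg - mean bg) equals
# `contrast` exactly when noise_sd = 0.  Noise can still clip at the
# boundary of [-1, 1].
compose_image <- function(mask, contrast, noise_sd, texture) {
  size <- nrow(mask)
  fg <- mask > 0
  img <- matrix(-contrast / 2, size, size)
  img[fg] <- contrast / 2
  amp <- min(texture$amplitude %||% 0, max(0, 1 - contrast / 2) / 3)
  if (amp > 0) {
    f <- pmin(pmax(smooth_field(size, texture$scale %||% 4), -2.5), 2.5)
    tf <- amp * f
    if (any(fg)) tf[fg] <- tf[fg] - mean(tf[fg])
    if (any(!fg)) tf[!fg] <- tf[!fg] - mean(tf[!fg])
    img <- img + tf
  }
  if (noise_sd > 0) {
    img <- img + noise_sd * matrix(stats::rnorm(size^2), size, size)
  }
  pmin(pmax(img, -1), 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic paired shape dataset
#'
#' Masks are drawn according to `shape_kind`; each image is a deterministic
#' function of its mask, the texture field and the noise draw, so a
#' mask-to-image mapping is learnable.  Generation is a pure function of
#' (config, seed).  Every non-degenerate mask has at least one foreground
#' and one background pixel (resampled if a draw comes out empty).
#'
#' @param config A [shape_dataset_config()].
#' @return A [seg_dataset()].
#' @examples
#' ds <- generate_shape_dataset(shape_dataset_config(n = 4, seed = 7))
#' length(ds)
#' @export
generate_shape_dataset <- function(config) {
  stopifnot(inherits(config, "shape_dataset_config"))
  size <- config$image_size
  g <- raster_grid(size)
  rasterize <- switch(config$shape_kind,
                      blob = mask_blob, ring = mask_ring, vessel = mask_vessel)
  pairs <- with_seed(config$seed, {
    lapply(seq_len(config$n), function(i) {
      m <- rasterize(size, g)
      tries <- 0L
      while ((!any(m) || all(m)) && tries < 20L) {
        m <- rasterize(size, g)
        tries <- tries + 1L
      }
      mask <- matrix(as.integer(m), size, size)
      img <- compose_image(mask, config$contrast, config$noise_sd, config$texture)
      mask_image_pair(img, mask, id = sprintf("%s-%03d", config$shape_kind, i))
    })
  })
  ds <- seg_dataset(pairs, split = config$split, label_count = 2L,
                    provenance = list(config = unclass(config)))
  if (!is.null(config$ood_shift)) {
    ds <- make_ood_variant(ds, config$ood_shift, seed = config$seed + 1L)
  }
  ds
}

#' Shift the appearance of a dataset out of domain
#'
#' Produces a variant whose images have shifted statistics while the masks
#' are preserved exactly, emulating evaluation data that originates from a
#' distinct acquisition.  The shift record may contain `intensity_bias`
#' (added everywhere), `contrast_delta` (added on the foreground), and
#' `texture` (`amplitude`, `scale`: a freshly drawn smooth field).  Values
#' are clipped to `[-1, 1]` after shifting; an all-zero shift returns the
#' images bit-identical.
#'
#' @param dataset A non-empty [seg_dataset()].
#' @param ood_shift List of shift components as above.
#' @param seed Integer seed for the texture draw.
#' @return A [seg_dataset()] of the same size.
#' @export
make_ood_variant <- function(dataset, ood_shift, seed = 1L) {
  stopifnot(inherits(dataset, "seg_dataset"))
  if (length(dataset$pairs) == 0L) stop("cannot shift an empty dataset")
  bias <- ood_shift$intensity_bias %||% 0
  cd <- ood_shift$contrast_delta %||% 0
  tex <- ood_shift$texture
  if (bias == 0 && cd == 0 && is.null(tex)) return(dataset)
  pairs <- with_seed(seed, {
    lapply(dataset$pairs, function(p) {
      img <- p$image + bias
      if (cd != 0) img[p$mask > 0] <- img[p$mask > 0] + cd
      if (!is.null(tex) && (tex$amplitude %||% 0) > 0) {
        img <- img + tex$amplitude * smooth_field(nrow(p$mask), tex$scale %||% 4)
      }
      mask_image_pair(pmin(pmax(img, -1), 1), p$mask, id = paste0(p$id, "-ood"),
                      label_count = p$label_count)
    })
  })
  seg_dataset(pairs, split = dataset$split, label_count = dataset$label_count,
              provenance = c(dataset$provenance, list(ood_shift = ood_shift)))
}

## ---- PNG and manifest I/O -------------------------------------------------

#' Write and read a mask-image pair as PNG files
#'
#' Images are mapped linearly from `[-1, 1]` to 8-bit gray (or RGB) PNG;
#' masks are written as 8-bit grayscale PNG whose pixel value equals the
#' integer label, which round-trips labels below 256 losslessly.  A
#' save-then-load round trip recovers the mask exactly and the image to
#' within the 8-bit quantization bound `1/127.5`.
#'
#' @param pair A [mask_image_pair()]; labels must fit in 8 bits.
#' @param image_path,mask_path Output/input file paths.
#' @param label_count Expected label count on load (validation).
#' @return `save_pair` returns the paths invisibly; `load_pair` returns a
#'   [mask_image_pair()].
#' @export
save_pair <- function(pair, image_path, mask_path) {
  stopifnot(inherits(pair, "mask_image_pair"))
  if (max(pair$mask) > 255L) stop("mask labels must fit in 8 bits")
  png::writePNG((pair$image + 1) / 2, image_path)
  png::writePNG(pair$mask / 255, mask_path)
  invisible(c(image = image_path, mask = mask_path))
}

#' @rdname save_pair
#' @param id Identifier for the loaded pair.
#' @export
load_pair <- function(image_path, mask_path, id = basename(image_path),
                      label_count = 2L) {
  img <- png::readPNG(image_path)
  msk <- png::readPNG(mask_path)
  if (length(dim(msk)) != 2L) stop("mask PNG must be single-channel")
  if (!identical(dim(img)[1:2], dim(msk))) {
    stop("image and mask PNG dimensions differ")
  }
  mask <- matrix(as.integer(round(msk * 255)), nrow(msk))
  if (any(mask >= label_count)) {
    stop("mask file contains label values outside {0..", label_count - 1L, "}")
  }
  mask_image_pair(img * 2 - 1, mask, id = id, label_count = label_count)
}

#' Save or load a dataset as PNG pairs plus a CSV manifest
#'
#' The manifest has columns `identifier`, `image_path`, `mask_path`,
#' `split` with paths relative to the manifest location.
#'
#' @param dataset A [seg_dataset()].
#' @param dir Output directory (created if needed).
#' @return `save_dataset` returns the manifest path invisibly;
#'   `load_dataset` returns a [seg_dataset()].
#' @export
save_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map(dataset$pairs, function(p) {
    ip <- paste0(p$id, "_img.png")
    mp <- paste0(p$id, "_mask.png")
    save_pair(p, file.path(dir, ip), file.path(dir, mp))
    tibble::tibble(identifier = p$id, image_path = ip, mask_path = mp,
                   split = dataset$split)
  })
  manifest <- dplyr::bind_rows(rows)
  path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, path)
  invisible(path)
}

#' @rdname save_dataset
#' @param manifest_path Path to a manifest CSV.
#' @param split Which split to load.
#' @param label_count Label count for validation.
#' @export
load_dataset <- function(manifest_path, split = "train", label_count = 2L) {
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE)
  manifest <- dplyr::filter(manifest, .data$split == !!split)
  base <- dirname(manifest_path)
  pairs <- purrr::pmap(manifest, function(identifier, image_path, mask_path, ...) {
    load_pair(file.path(base, image_path), file.path(base, mask_path),
              id = identifier, label_count = label_count)
  })
  seg_dataset(pairs, split = if (split == "val") "validation" else split,
              label_count = label_count,
              provenance = list(manifest = manifest_path))
}
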