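# Mask augmentation for reverse (mask-first) generation.
#
# Real annotated masks are perturbed - rotation, flipping, translation, and
# optionally elastic deformation, applied in a random sequence - and the
# augmented mask is fed to the mask-to-image generator.  All warps use
# nearest-neighbour sampling with background (label 0) fill, so integer
# label semantics are preserved and no phantom classes appear.
# Coordinates are documented 0-based row-major: pixel (r, c) = (row from
# top, column from left).

#' Mask augmentation configuration
#'
#' Defaults sit mid-range across operator ablations: rotations in
#' (-15, 15) degrees, both flips at probability 0.5, translations up to 10%
#' of the side, elastic deformation disabled.  For thin vessel-like
#' structures a small-angle range (-5, 5) is recommended.
#'
#' @param rotation_range Length-2 numeric `(lo, hi)` in degrees, `lo <= hi`.
#' @param flip_horizontal_p,flip_vertical_p Flip probabilities in `[0, 1]`.
#' @param translate_fraction Maximum shift as a fraction of the side, in
#'   `[0, 1)`.
#' @param elastic `NULL`, or list with `alpha` (displacement magnitude, px)
#'   and `sigma` (smoothing length, px).
#' @param enabled_ops Subset of `c("rotate", "flip", "translate", "elastic")`.
#' @param randomize_order Draw the operator order uniformly at random.
#' @return An `augment_config` object.
#' @export
augment_config <- function(rotation_range = c(-15, 15),
                           flip_horizontal_p = 0.5, flip_vertical_p = 0.5,
                           translate_fraction = 0.1, elastic = NULL,
                           enabled_ops = c("rotate", "flip", "translate"),
                           randomize_order = TRUE) {
  stopifnot(length(rotation_range) == 2L, rotation_range[1] <= rotation_range[2],
            flip_horizontal_p >= 0, flip_horizontal_p <= 1,
            flip_vertical_p >= 0, flip_vertical_p <= 1,
            translate_fraction >= 0, translate_fraction < 1)
  ops <- if (length(enabled_ops) == 0L) character(0) else {
    match.arg(enabled_ops, c("rotate", "flip", "translate", "elastic"),
              several.ok = TRUE)
  }
  if (!is.null(elastic)) {
    stopifnot(elastic$alpha >= 0)
    if (elastic$sigma <= 0) stop("elastic sigma must be positive")
  }
  structure(list(rotation_range = rotation_range,
                 flip_horizontal_p = flip_horizontal_p,
                 flip_vertical_p = flip_vertical_p,
                 translate_fraction = translate_fraction,
                 elastic = elastic, enabled_ops = ops,
                 randomize_order = isTRUE(randomize_order)),
            class = "augment_config")
}

#' Flip a mask along an image axis
#'
#' Horizontal flips map pixel `(r, c)` to `(r, W-1-c)`; vertical flips map
#' `(r, c)` to `(H-1-r, c)` (0-based).  The label multiset is preserved and
#' flipping twice along the same axis is the identity.
#'
#' @param mask Integer `H x W` matrix.
#' @param axis `"horizontal"` (mirror left-right) or `"vertical"`.
#' @return The flipped mask.
#' @export
flip_mask <- function(mask, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  if (axis == "horizontal") mask[, ncol(mask):1, drop = FALSE]
  else mask[nrow(mask):1, , drop = FALSE]
}

#' Rotate a mask about the image centre
#'
#' Rotation by `angle_degrees` counterclockwise in standard image axes
#' (x = columns rightward, y = rows downward rotates clockwise on screen
#' for positive angles; the inverse map is applied per output pixel).
#' Nearest-neighbour sampling with background fill keeps the output label
#' set inside the input set plus `{0}`; output dimensions equal the input.
#'
#' @param mask Integer `H x W` matrix.
#' @param angle_degrees Any real angle; 0 is the identity.
#' @return The rotated mask.
#' @export
rotate_mask <- function(mask, angle_degrees) {
  if (angle_degrees %% 360 == 0) return(mask)
  H <- nrow(mask); W <- ncol(mask)
  th <- angle_degrees * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  g <- raster_grid(max(H, W))
  r <- g$r[seq_len(H), seq_len(W)] - cy
  c <- g$c[seq_len(H), seq_len(W)] - cx
  # inverse rotation of output coordinates into the source frame
  sr <- round(cos(th) * r - sin(th) * c + cy)
  sc <- round(sin(th) * r + cos(th) * c + cx)
  out <- matrix(0L, H, W)
  ok <- sr >= 1 & sr <= H & sc >= 1 & sc <= W
  out[ok] <- mask[cbind(sr[ok], sc[ok])]
  out
}

#' Translate a mask by whole pixels
#'
#' Pixel `(r, c)` moves to `(r + dy, c + dx)`; content shifted beyond the
#' border is discarded and vacated pixels are filled with background 0.
#'
#' @param mask Integer `H x W` matrix.
#' @param dy,dx Integer shifts with `|dy| < H`, `|dx| < W`.
#' @return The translated mask.
#' @export
translate_mask <- function(mask, dy, dx) {
  H <- nrow(mask); W <- ncol(mask)
  dy <- as.integer(round(dy)); dx <- as.integer(round(dx))
  if (abs(dy) >= H || abs(dx) >= W) {
    stop("shift magnitude must be smaller than the image size")
  }
  out <- matrix(0L, H, W)
  src_r <- seq_len(H) - dy
  src_c <- seq_len(W) - dx
  ok_r <- src_r >= 1 & src_r <= H
  ok_c <- src_c >= 1 & src_c <= W
  out[ok_r, ok_c] <- mask[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

#' Elastically deform a mask
#'
#' A smooth random displacement field (white noise smoothed by a Gaussian
#' of width `sigma`, scaled to maximum magnitude `alpha` pixels) is applied
#' with nearest-neighbour sampling and background fill.
#'
#' @param mask Integer `H x W` matrix.
#' @param alpha Displacement magnitude in pixels (>= 0); 0 is the identity.
#' @param sigma Smoothing length in pixels (> 0).
#' @param seed Optional integer seed; the deformation is deterministic
#'   given the seed.
#' @return The deformed mask.
#' @export
elastic_deform_mask <- function(mask, alpha, sigma, seed = NULL) {
  if (sigma <= 0) stop("sigma must be positive")
  if (alpha < 0) stop("alpha must be non-negative")
  if (alpha == 0) return(mask)
  H <- nrow(mask); W <- ncol(mask)
  draw <- function() {
    f <- gauss_band(H, sigma) %*% matrix(stats::rnorm(H * W), H, W) %*%
      t(gauss_band(W, sigma))
    f / max(abs(f), 1e-12) * alpha
  }
  fields <- if (is.null(seed)) list(draw(), draw()) else {
    with_seed(seed, list(draw(), draw()))
  }
  g <- raster_grid(max(H, W))
  sr <- round(g$r[seq_len(H), seq_len(W)] + fields[[1L]])
  sc <- round(g$c[seq_len(H), seq_len(W)] + fields[[2L]])
  out <- matrix(0L, H, W)
  ok <- sr >= 1 & sr <= H & sc >= 1 & sc <= W
  out[ok] <- mask[cbind(sr[ok], sc[ok])]
  out
}

#' Apply the configured augmentation operators in a random sequence
#'
#' Samples parameters from the configured ranges, applies the enabled
#' operators in an order drawn uniformly at random (when
#' `randomize_order`), and returns the augmented mask.  A fixed seed makes
#' the output reproducible; with all operators disabled the input is
#' returned unchanged.
#'
#' @param mask Integer `H x W` matrix.
#' @param config An [augment_config()].
#' @param seed Optional integer seed.
#' @return The augmented mask (same dimensions, labels within the input
#'   set plus background).
#' @export
augment_mask <- function(mask, config, seed = NULL) {
  stopifnot(inherits(config, "augment_config"))
  run <- function() {
    ops <- config$enabled_ops
    if (length(ops) == 0L) return(mask)
    if (config$randomize_order) ops <- sample(ops)
    m <- mask
    for (op in ops) {
      m <- switch(op,
        rotate = rotate_mask(m, stats::runif(1, config$rotation_range[1],
                                             config$rotation_range[2])),
        flip = {
          if (stats::runif(1) < config$flip_horizontal_p) m <- flip_mask(m, "horizontal")
          if (stats::runif(1) < config$flip_vertical_p) m <- flip_mask(m, "vertical")
          m
        },
        translate = {
          mx <- config$translate_fraction
          translate_mask(m,
                         dy = round(stats::runif(1, -mx, mx) * nrow(m)),
                         dx = round(stats::runif(1, -mx, mx) * ncol(m)))
        },
        elastic = {
          if (is.null(config$elastic)) m else {
            elastic_deform_mask(m, config$elastic$alpha, config$elastic$sigma)
          }
        })
    }
    m
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Apply identical sampled augmentation to an image and its mask
#'
#' Baseline comparator: the same sampled parameters are applied to both the
#' input image and the output mask (classic paired augmentation).  The
#' image is warped with the same nearest-neighbour maps as the mask.
#'
#' @param pair A [mask_image_pair()].
#' @param config An [augment_config()].
#' @param seed Optional integer seed.
#' @return A [mask_image_pair()].
#' @export
augment_pair <- function(pair, config, seed = NULL) {
  stopifnot(inherits(pair, "mask_image_pair"), inherits(config, "augment_config"))
  run <- function() {
    ops <- config$enabled_ops
    img <- pair$image; m <- pair$mask
    if (length(ops) == 0L) return(list(img, m))
    if (config$randomize_order) ops <- sample(ops)
    for (op in ops) {
      if (op == "rotate") {
        a <- stats::runif(1, config$rotation_range[1], config$rotation_range[2])
        m <- rotate_mask(m, a)
        img <- rotate_image_nn(img, a)
      } else if (op == "flip") {
        if (stats::runif(1) < config$flip_horizontal_p) {
          m <- flip_mask(m, "horizontal"); img <- img[, ncol(img):1, drop = FALSE]
        }
        if (stats::runif(1) < config$flip_vertical_p) {
          m <- flip_mask(m, "vertical"); img <- img[nrow(img):1, , drop = FALSE]
        }
      } else if (op == "translate") {
        mx <- config$translate_fraction
        dy <- round(stats::runif(1, -mx, mx) * nrow(m))
        dx <- round(stats::runif(1, -mx, mx) * ncol(m))
        m <- translate_mask(m, dy, dx)
        img <- translate_image(img, dy, dx)
      }
    }
    list(img, m)
  }
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  mask_image_pair(res[[1L]], res[[2L]], id = paste0(pair$id, "-aug"),
                  label_count = pair$label_count)
}

rotate_image_nn <- function(img, angle_degrees) {
  if (angle_degrees %% 360 == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  th <- angle_degrees * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  g <- raster_grid(max(H, W))
  r <- g$r[seq_len(H), seq_len(W)] - cy
  c <- g$c[seq_len(H), seq_len(W)] - cx
  sr <- round(cos(th) * r - sin(th) * c + cy)
  sc <- round(sin(th) * r + cos(th) * c + cx)
  out <- matrix(0, H, W)
  ok <- sr >= 1 & sr <= H & sc >= 1 & sc <= W
  out[ok] <- img[cbind(sr[ok], sc[ok])]
  out
}

translate_image <- function(img, dy, dx) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  src_r <- seq_len(H) - dy
  src_c <- seq_len(W) - dx
  ok_r <- src_r >= 1 & src_r <= H
  ok_c <- src_c >= 1 & src_c <= W
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}
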