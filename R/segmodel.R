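#' Build the reference U-Net segmentation backbone
#'
#' A compact encoder-decoder with mirrored skip connections: strided 4-2-1
#' convolutions with instance normalization and leaky rectifiers on the way
#' down, transposed 4-2-1 convolutions with rectifiers on the way up, and a
#' 1x1 head emitting per-pixel scores over the `label_count` classes at the
#' input resolution.  The trilevel solver is backbone-agnostic: any model
#' honouring the same forward contract (image in, `L x H x W` scores out)
#' can be registered via [register_backbone()].
#'
#' @param image_size Side length in pixels, divisible by `2^depth`.
#' @param channels Image channel count.
#' @param label_count Number of classes `L` (>= 2).
#' @param base_width First-layer channel width.
#' @param depth Encoder depth.
#' @param seed Integer seed for weight initialization.
#' @return A `segmenter` model object.
#' @export
build_unet <- function(image_size, channels = 1L, label_count = 2L,
                       base_width = 8L, depth = 2L, seed = 1L) {
  if (label_count < 2L) stop("label_count must be at least 2")
  if (depth < 1L) stop("depth must be at least 1")
  if (image_size %% 2L^depth != 0L) {
    stop("image_size ", image_size, " is not divisible by 2^depth = ", 2L^depth)
  }
  plan <- gen_channel_plan(channels, depth, base_width)
  params <- list()
  with_seed(seed, {
    for (d in seq_len(depth)) {
      cin <- plan$cw[d]; cout <- plan$cw[d + 1L]
      params[[paste0("enc", d, ".w")]] <- init_array(c(cout, cin, 4L, 4L), cin * 16L)
      params[[paste0("enc", d, ".bias")]] <- numeric(cout)
    }
    for (j in seq_len(depth)) {
      cin <- if (j == 1L) plan$cw[depth + 1L] else {
        plan$dec_out[j - 1L] + plan$cw[depth - j + 2L]
      }
      cout <- plan$dec_out[j]
      params[[paste0("dec", j, ".w")]] <- init_array(c(cin, cout, 4L, 4L), cin * 16L)
      params[[paste0("dec", j, ".bias")]] <- numeric(cout)
    }
    params[["head.w"]] <- init_array(c(label_count, plan$dec_out[depth]),
                                     plan$dec_out[depth])
    params[["head.bias"]] <- numeric(label_count)
  })
  structure(list(
    params = params,
    config = list(image_size = as.integer(image_size), channels = as.integer(channels),
                  label_count = as.integer(label_count),
                  base_width = as.integer(base_width), depth = as.integer(depth),
                  plan = plan)
  ), class = "segmenter")
}

# U-Net forward on graph nodes; img: (C x B*H*W) node
seg_forward_graph <- function(seg, params, img, B) {
  cfg <- seg$config
  plan <- cfg$plan
  depth <- cfg$depth
  Hs <- cfg$image_size; Ws <- cfg$image_size; Cs <- cfg$channels
  x <- img
  enc <- vector("list", depth)
  for (d in seq_len(depth)) {
    cv <- nn_conv2d(x, params[[paste0("enc", d, ".w")]],
                    params[[paste0("enc", d, ".bias")]],
                    Hs, Ws, Cs, B, 4L, 2L, 1L)
    x <- ad_lrelu(nn_instance_norm(cv$y, cv$C, B, cv$H * cv$W), 0.2)
    Hs <- cv$H; Ws <- cv$W; Cs <- cv$C
    enc[[d]] <- list(x = x, H = Hs, W = Ws, C = Cs)
  }
  for (j in seq_len(depth)) {
    if (j > 1L) {
      sk <- enc[[depth - j + 1L]]
      x <- ad_rbind(x, sk$x)
      Cs <- Cs + sk$C
    }
    up <- nn_upconv2d(x, params[[paste0("dec", j, ".w")]],
                      params[[paste0("dec", j, ".bias")]],
                      Hs, Ws, Cs, B, 4L, 2L, 1L)
    x <- ad_relu(nn_instance_norm(up$y, up$C, B, up$H * up$W))
    Hs <- up$H; Ws <- up$W; Cs <- up$C
  }
  ad_affine(params[["head.w"]], x, params[["head.bias"]])
}

#' Per-pixel class scores for a batch of images
#'
#' @param segmenter A [build_unet()] model (or registered backbone instance).
#' @param images A single image (`H x W` matrix or `H x W x C` array) or a
#'   list of them.
#' @return For each image, an `L x H x W` array of unnormalized scores;
#'   a single array if a single image was given.
#' @export
seg_scores <- function(segmenter, images) {
  single <- !is.list(images)
  if (single) images <- list(images)
  B <- length(images)
  cfg <- segmenter$config
  img <- ad_const(stack_images(images))
  pn <- leaf_params(segmenter$params, requires_grad = FALSE)
  sc <- seg_forward_graph(segmenter, pn, img, B)$value
  out <- lapply(seq_len(B), function(b) {
    cols <- (b - 1L) * cfg$image_size^2 + seq_len(cfg$image_size^2)
    array(sc[, cols], dim = c(cfg$label_count, cfg$image_size, cfg$image_size))
  })
  if (single) out[[1L]] else out
}

#' Predict label masks by per-pixel argmax
#'
#' Score ties are broken in favour of the lowest class index.
#'
#' @inheritParams seg_scores
#' @return Integer mask(s) with values in `{0, ..., L-1}`.
#' @export
predict_mask <- function(segmenter, images) {
  single <- !is.list(images)
  scores <- seg_scores(segmenter, images)
  if (single) scores <- list(scores)
  out <- lapply(scores, function(sc) {
    L <- dim(sc)[1L]
    flat <- matrix(sc, L)
    matrix(max.col(t(flat), ties.method = "first") - 1L,
           dim(sc)[2L], dim(sc)[3L])
  })
  if (single) out[[1L]] else out
}

#' Pixel-wise cross-entropy segmentation loss
#'
#' Mean over all pixels of the cross-entropy between the softmax of the
#' scores and the integer labels.
#'
#' @param scores `L x H x W` array (or `L x N` matrix) of class scores.
#' @param mask `H x W` integer mask (or length-`N` labels) in `{0..L-1}`.
#' @return Non-negative scalar.
#' @examples
#' sc <- array(0, dim = c(2, 3, 3))            # uniform scores, L = 2
#' seg_loss(sc, matrix(0L, 3, 3))              # = log(2)
#' @export
seg_loss <- function(scores, mask) {
  L <- dim(scores)[1L]
  flat <- matrix(scores, L)
  labs <- as.vector(mask)
  if (length(labs) != ncol(flat)) stop("scores and mask sizes disagree")
  if (any(labs < 0 | labs >= L)) stop("mask label outside {0..", L - 1L, "}")
  nn_softmax_ce(ad_const(flat), labs)$value
}

## ---- overlap metrics ------------------------------------------------------

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must have identical shape")
}

#' Dice overlap between two label masks
#'
#' `2|A ∩ B| / (|A| + |B|)` for the given positive label, where A and B are
#' the predicted and reference foreground sets.  When both sets are empty
#' the score is defined as 1 (perfect agreement on "nothing to segment").
#'
#' @param pred_mask,gt_mask Integer masks of identical shape.
#' @param positive_label Label defining the foreground set.
#' @return A number in `[0, 1]`.
#' @examples
#' m <- matrix(c(1, 1, 0, 0), 2)
#' dice_score(m, m)   # 1
#' @export
dice_score <- function(pred_mask, gt_mask, positive_label = 1L) {
  check_same_shape(pred_mask, gt_mask)
  a <- pred_mask == positive_label
  b <- gt_mask == positive_label
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Jaccard index (intersection-over-union) between two label masks
#'
#' `|A ∩ B| / |A ∪ B|`; defined as 1 when both sets are empty.  Related to
#' the Dice score by `J = D / (2 - D)`.
#'
#' @inheritParams dice_score
#' @return A number in `[0, 1]`.
#' @export
jaccard_index <- function(pred_mask, gt_mask, positive_label = 1L) {
  check_same_shape(pred_mask, gt_mask)
  a <- pred_mask == positive_label
  b <- gt_mask == positive_label
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

metric_fn <- function(metric = c("dice", "jaccard")) {
  metric <- match.arg(metric)
  if (metric == "dice") dice_score else jaccard_index
}

## ---- backbone registry ----------------------------------------------------

.backbones <- new.env(parent = emptyenv())

#' Register or fetch a segmentation backbone builder
#'
#' Mirrors the pluggable-backbone design: the trilevel solver only relies on
#' the forward contract, so alternative architectures can be registered by
#' name and selected from the run configuration.
#'
#' @param name Backbone name.
#' @param builder A function with the signature of [build_unet()].
#' @return `register_backbone` returns the builder invisibly;
#'   `get_backbone` returns the registered builder.
#' @export
register_backbone <- function(name, builder) {
  stopifnot(is.character(name), is.function(builder))
  assign(name, builder, envir = .backbones)
  invisible(builder)
}

#' @rdname register_backbone
#' @export
get_backbone <- function(name) {
  if (!exists(name, envir = .backbones, inherits = FALSE)) {
    stop("unknown backbone '", name, "'")
  }
  get(name, envir = .backbones, inherits = FALSE)
}
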