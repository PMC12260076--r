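#' Candidate operator pool for searchable cells
#'
#' The shipped pool holds kernel/stride/padding triplets 4-2-1, 6-2-2 and
#' 8-2-3.  Each satisfies `kernel - 2*padding == stride == 2`, so every
#' candidate in a cell maps an input of a given spatial size to the same
#' output size: halving it for convolution cells and doubling it for
#' transposed-convolution cells.  All candidates of a cell can therefore be
#' mixed by convex selection weights.
#'
#' @return A list of `K` candidate descriptors, each with fields `kernel`,
#'   `stride` and `padding`.
#' @export
default_candidate_pool <- function() {
  list(list(kernel = 4L, stride = 2L, padding = 1L),
       list(kernel = 6L, stride = 2L, padding = 2L),
       list(kernel = 8L, stride = 2L, padding = 3L))
}

check_pool <- function(pool) {
  stopifnot(length(pool) >= 1L)
  for (cand in pool) {
    if (cand$kernel - 2L * cand$padding != cand$stride) {
      stop("candidate (", cand$kernel, ",", cand$stride, ",", cand$padding,
           ") is not shape-compatible: kernel - 2*padding must equal stride")
    }
  }
  invisible(pool)
}

#' Normalize architecture logits to selection weights
#'
#' Selection weights live in `[0, 1]` and sum to one within each cell; the
#' unconstrained parameterization is a per-cell softmax over logits, which
#' keeps the operator mixture convex and differentiable.
#'
#' @param logits Numeric vector (one cell) or `K x n_cells` matrix.
#' @return Object of the same shape with columns (cells) summing to 1.
#' @examples
#' normalize_alphas(c(0, 0, 0))        # uniform 1/3
#' normalize_alphas(matrix(0, 3, 4))   # one column per cell
#' @export
normalize_alphas <- function(logits) {
  if (!all(is.finite(logits))) stop("non-finite architecture logits")
  if (is.matrix(logits)) softmax_cols(logits) else as.vector(softmax_cols(matrix(logits)))
}

#' Architecture selection weights
#'
#' Holds the unconstrained per-cell logits and, after [discretize_architecture()],
#' an optional hard selection.  `alphas_of()` returns the effective mixture
#' weights: softmax of the logits, or an exact one-hot when discretized.
#'
#' @param logits `K x n_cells` numeric matrix of unconstrained logits.
#' @param cell_names Optional character vector naming the cells.
#' @return An `arch_weights` object.
#' @export
arch_weights <- function(logits, cell_names = NULL) {
  stopifnot(is.matrix(logits), all(is.finite(logits)))
  if (!is.null(cell_names)) colnames(logits) <- cell_names
  structure(list(logits = logits, onehot = NULL), class = "arch_weights")
}

#' @rdname arch_weights
#' @param arch An `arch_weights` object.
#' @export
alphas_of <- function(arch) {
  if (!is.null(arch$onehot)) {
    a <- matrix(0, nrow(arch$logits), ncol(arch$logits),
                dimnames = dimnames(arch$logits))
    a[cbind(arch$onehot, seq_len(ncol(a)))] <- 1
    return(a)
  }
  normalize_alphas(arch$logits)
}

#' @export
print.arch_weights <- function(x, ...) {
  cat("<arch_weights: ", ncol(x$logits), " cells x K=", nrow(x$logits),
      if (!is.null(x$onehot)) " (discretized)", ">\n", sep = "")
  print(round(alphas_of(x), 3))
  invisible(x)
}

#' Retain the most influential operator per cell
#'
#' Replaces each cell's mixture by a hard selection of the candidate with
#' the largest selection weight.  Ties are broken deterministically in
#' favour of the lowest candidate index.
#'
#' @param arch An [arch_weights()] object.
#' @return An `arch_weights` object whose effective weights are one-hot.
#' @export
discretize_architecture <- function(arch) {
  a <- alphas_of(arch)
  arch$onehot <- apply(a, 2L, which.max)   # which.max: first max wins ties
  arch
}

## ---- searchable generator -------------------------------------------------

gen_channel_plan <- function(label_count, depth, base_width) {
  enc_out <- as.integer(base_width * 2^(seq_len(depth) - 1L))
  cw <- c(as.integer(label_count), enc_out)
  dec_out <- vapply(seq_len(depth), function(j) {
    if (j < depth) as.integer(base_width * 2^(depth - j - 1L)) else as.integer(base_width)
  }, integer(1))
  list(cw = cw, dec_out = dec_out)
}

init_cell_params <- function(prefix, pool, cin, cout, transposed) {
  params <- list()
  for (k in seq_along(pool)) {
    kk <- pool[[k]]$kernel
    dm <- if (transposed) c(cin, cout, kk, kk) else c(cout, cin, kk, kk)
    params[[paste0(prefix, ".b", k, ".w")]] <- init_array(dm, cin * kk * kk)
    params[[paste0(prefix, ".b", k, ".bias")]] <- numeric(cout)
  }
  params
}

#' Build a searchable mask-to-image generator
#'
#' The generator is an encoder-decoder of searchable cells.  Each encoder
#' cell mixes `K` strided-convolution candidates (halving resolution), each
#' decoder cell mixes `K` transposed-convolution candidates (doubling it);
#' the mixture weights are held in a separate [arch_weights()] object.
#' Every branch is followed by instance normalization and a leaky (encoder)
#' or plain (decoder) rectifier, mirrored skip connections are concatenated
#' by default, and a final 1x1 projection with `tanh` squashes the output
#' image into `[-1, 1]`.  Masks enter as one-hot label channels.
#'
#' @param image_size Side length in pixels; must be divisible by `2^depth`.
#' @param channels Image channel count (1 = grayscale).
#' @param depth Number of encoder (and decoder) cells; must be >= 1.
#' @param base_width Channel width of the first encoder cell.
#' @param skip Concatenate mirrored encoder features in the decoder.
#' @param label_count Number of mask labels `L`.
#' @param pool Candidate operator pool, see [default_candidate_pool()].
#' @param seed Integer seed for weight initialization.
#' @return List with elements `generator` (model object) and `arch`
#'   ([arch_weights()] initialized to equal logits).
#' @export
build_searchable_generator <- function(image_size, channels = 1L, depth = 2L,
                                       base_width = 8L, skip = TRUE,
                                       label_count = 2L,
                                       pool = default_candidate_pool(),
                                       seed = 1L) {
  if (depth < 1L) stop("depth must be at least 1")
  if (image_size %% 2L^depth != 0L) {
    stop("image_size ", image_size, " is not divisible by 2^depth = ", 2L^depth)
  }
  check_pool(pool)
  K <- length(pool)
  plan <- gen_channel_plan(label_count, depth, base_width)

  params <- list()
  cell_names <- character(0)
  with_seed(seed, {
    for (d in seq_len(depth)) {
      params <- c(params, init_cell_params(
        paste0("enc", d), pool, plan$cw[d], plan$cw[d + 1L], transposed = FALSE))
      cell_names <- c(cell_names, paste0("enc", d))
    }
    for (j in seq_len(depth)) {
      cin <- if (j == 1L) plan$cw[depth + 1L] else {
        plan$dec_out[j - 1L] + if (skip) plan$cw[depth - j + 2L] else 0L
      }
      params <- c(params, init_cell_params(
        paste0("dec", j), pool, cin, plan$dec_out[j], transposed = TRUE))
      cell_names <- c(cell_names, paste0("dec", j))
    }
    params[["head.w"]] <- init_array(c(channels, plan$dec_out[depth]),
                                     plan$dec_out[depth])
    params[["head.bias"]] <- numeric(channels)
  })

  gen <- structure(list(
    params = params,
    config = list(image_size = as.integer(image_size), channels = as.integer(channels),
                  depth = as.integer(depth), base_width = as.integer(base_width),
                  skip = isTRUE(skip), label_count = as.integer(label_count),
                  pool = pool, plan = plan)
  ), class = "searchable_generator")

  logits <- matrix(0, K, 2L * depth)
  list(generator = gen, arch = arch_weights(logits, cell_names))
}

# alpha-weighted sum of the K candidate branches of one cell (graph nodes)
cell_mix_forward <- function(x, params, prefix, alphas, cell_index, pool,
                             H, W, Cin, B, transposed) {
  K <- length(pool)
  out <- NULL
  shape <- NULL
  for (k in seq_len(K)) {
    cand <- pool[[k]]
    w <- params[[paste0(prefix, ".b", k, ".w")]]
    b <- params[[paste0(prefix, ".b", k, ".bias")]]
    br <- if (transposed) {
      nn_upconv2d(x, w, b, H, W, Cin, B, cand$kernel, cand$stride, cand$padding)
    } else {
      nn_conv2d(x, w, b, H, W, Cin, B, cand$kernel, cand$stride, cand$padding)
    }
    a_k <- ad_gather(alphas, k + K * (cell_index - 1L), 1L)
    term <- ad_scalar_mul(a_k, br$y)
    out <- if (is.null(out)) term else ad_add(out, term)
    shape <- br
  }
  list(y = out, H = shape$H, W = shape$W, C = shape$C)
}

# full generator forward on graph nodes
# params: named list of nodes; alphas: (K x 2*depth) node; mask1h: const node
gen_forward_graph <- function(gen, params, alphas, mask1h, B) {
  cfg <- gen$config
  pool <- cfg$pool
  depth <- cfg$depth
  plan <- cfg$plan
  H <- cfg$image_size; W <- cfg$image_size

  x <- mask1h
  enc <- vector("list", depth)
  Hs <- H; Ws <- W; Cs <- cfg$label_count
  for (d in seq_len(depth)) {
    cell <- cell_mix_forward(x, params, paste0("enc", d), alphas, d, pool,
                             Hs, Ws, Cs, B, transposed = FALSE)
    y <- nn_instance_norm(cell$y, cell$C, B, cell$H * cell$W)
    x <- ad_lrelu(y, 0.2)
    Hs <- cell$H; Ws <- cell$W; Cs <- cell$C
    enc[[d]] <- list(x = x, H = Hs, W = Ws, C = Cs)
  }

  for (j in seq_len(depth)) {
    if (j > 1L) {
      sk <- enc[[depth - j + 1L]]
      if (cfg$skip) {
        x <- ad_rbind(x, sk$x)
        Cs <- Cs + sk$C
      }
    }
    cell <- cell_mix_forward(x, params, paste0("dec", j), alphas, depth + j,
                             pool, Hs, Ws, Cs, B, transposed = TRUE)
    y <- nn_instance_norm(cell$y, cell$C, B, cell$H * cell$W)
    x <- ad_relu(y)
    Hs <- cell$H; Ws <- cell$W; Cs <- cell$C
  }

  ad_tanh(ad_affine(params[["head.w"]], x, params[["head.bias"]]))
}

#' Generate images from masks with the current architecture
#'
#' Deterministic given the generator weights, the selection weights and the
#' masks: the mask is one-hot encoded, passed through the mixed cells, and
#' squashed to `[-1, 1]`.
#'
#' @param generator A `searchable_generator`.
#' @param arch An [arch_weights()] object (continuous or discretized).
#' @param masks A single `H x W` integer mask or a list of them.
#' @return An image (matrix `H x W`, or `H x W x C` array) or list thereof,
#'   matching the input form.
#' @export
generate_image <- function(generator, arch, masks) {
  single <- !is.list(masks)
  if (single) masks <- list(masks)
  cfg <- generator$config
  for (m in masks) {
    if (!all(dim(m) == c(cfg$image_size, cfg$image_size))) {
      stop("mask dimensions do not match the generator's configured size")
    }
  }
  B <- length(masks)
  m1h <- ad_const(onehot_masks(masks, cfg$label_count))
  pn <- leaf_params(generator$params, requires_grad = FALSE)
  an <- ad_const(alphas_of(arch))
  img <- gen_forward_graph(generator, pn, an, m1h, B)
  out <- unstack_images(img$value, cfg$image_size, cfg$image_size, B)
  if (single) out[[1L]] else out
}

## ---- discriminator --------------------------------------------------------

#' Build the (fixed-architecture) discriminator
#'
#' A small patch-style convolutional classifier: two strided convolutions
#' with leaky rectifiers (instance norm on the second) and a 1x1 head that
#' emits one logit per patch.  By default it is conditioned on the input
#' mask by channel concatenation; probabilities are obtained by a logistic
#' transform of the patch logits.
#'
#' @param image_size Side length in pixels (divisible by 4).
#' @param channels Image channels.
#' @param label_count Mask labels (used when `conditional`).
#' @param base_width First-layer channel width.
#' @param conditional Condition on the mask via channel concatenation.
#' @param seed Integer seed for weight initialization.
#' @return A `discriminator` model object.
#' @export
build_discriminator <- function(image_size, channels = 1L, label_count = 2L,
                                base_width = 8L, conditional = TRUE, seed = 1L) {
  if (image_size %% 4L != 0L) stop("image_size must be divisible by 4")
  cin <- channels + if (conditional) label_count else 0L
  params <- list()
  with_seed(seed, {
    params[["c1.w"]] <- init_array(c(base_width, cin, 4L, 4L), cin * 16L)
    params[["c1.bias"]] <- numeric(base_width)
    params[["c2.w"]] <- init_array(c(2L * base_width, base_width, 4L, 4L),
                                   base_width * 16L)
    params[["c2.bias"]] <- numeric(2L * base_width)
    params[["head.w"]] <- init_array(c(1L, 2L * base_width), 2L * base_width)
    params[["head.bias"]] <- numeric(1L)
  })
  structure(list(
    params = params,
    config = list(image_size = as.integer(image_size), channels = as.integer(channels),
                  label_count = as.integer(label_count),
                  base_width = as.integer(base_width),
                  conditional = isTRUE(conditional))
  ), class = "discriminator")
}

# img: (C x B*H*W) node; mask1h: const node or NULL
disc_forward_graph <- function(disc, params, img, mask1h, B) {
  cfg <- disc$config
  x <- if (cfg$conditional) {
    if (is.null(mask1h)) stop("conditional discriminator needs the mask")
    ad_rbind(img, mask1h)
  } else img
  H <- cfg$image_size; W <- cfg$image_size
  cin <- cfg$channels + if (cfg$conditional) cfg$label_count else 0L

  c1 <- nn_conv2d(x, params[["c1.w"]], params[["c1.bias"]], H, W, cin, B, 4L, 2L, 1L)
  x <- ad_lrelu(c1$y, 0.2)
  c2 <- nn_conv2d(x, params[["c2.w"]], params[["c2.bias"]], c1$H, c1$W, c1$C, B,
                  4L, 2L, 1L)
  x <- ad_lrelu(nn_instance_norm(c2$y, c2$C, B, c2$H * c2$W), 0.2)
  ad_affine(params[["head.w"]], x, params[["head.bias"]])
}

## ---- adversarial losses ---------------------------------------------------

#' Adversarial cross-entropy losses from classification probabilities
#'
#' Closed-form helpers used both by [gan_losses()] and as arithmetic
#' reference in tests.  The discriminator loss averages the two binary
#' cross-entropy terms, `L_d = -(mean log p_real + mean log(1 - p_fake))/2`;
#' the generator loss is the non-saturating form `L_g = -mean log p_fake`.
#'
#' @param p_real,p_fake Probabilities the discriminator assigns to real
#'   (resp. fake) inputs being real; vectors of any positive length.
#' @return Named list with `l_d`, `l_g` and the two discriminator terms
#'   `bce_real`, `bce_fake`.
#' @export
gan_loss_terms <- function(p_real, p_fake) {
  stopifnot(length(p_real) > 0L, length(p_fake) > 0L)
  bce_real <- -mean(log(p_real))
  bce_fake <- -mean(log(1 - p_fake))
  list(l_d = (bce_real + bce_fake) / 2,
       l_g = -mean(log(p_fake)),
       bce_real = bce_real, bce_fake = bce_fake)
}

#' Adversarial losses of a discriminator on real and generated pairs
#'
#' @param discriminator A [build_discriminator()] model.
#' @param real_pairs,fake_pairs Non-empty lists of pairs, each a list with
#'   elements `image` and `mask`.
#' @return As [gan_loss_terms()].
#' @export
gan_losses <- function(discriminator, real_pairs, fake_pairs) {
  if (length(real_pairs) == 0L || length(fake_pairs) == 0L) {
    stop("gan_losses needs non-empty real and fake batches")
  }
  score <- function(pairs) {
    B <- length(pairs)
    img <- ad_const(stack_images(lapply(pairs, `[[`, "image")))
    m1h <- if (discriminator$config$conditional) {
      ad_const(onehot_masks(lapply(pairs, `[[`, "mask"),
                            discriminator$config$label_count))
    } else NULL
    pn <- leaf_params(discriminator$params, requires_grad = FALSE)
    stats::plogis(as.vector(
      disc_forward_graph(discriminator, pn, img, m1h, B)$value))
  }
  gan_loss_terms(score(real_pairs), score(fake_pairs))
}

# graph-node adversarial objectives from real/fake patch logits:
#   minimax value  L_mm  = mean log sigma(d_real) + mean log(1 - sigma(d_fake))
#   (ascended by H, descended by G in the virtual steps)
#   practical committed losses: l_d = BCE average, l_g non-saturating
gan_graph_losses <- function(d_real, d_fake) {
  bce_real <- ad_mean(ad_softplus(ad_neg(d_real)))   # -mean log sigma(d_real)
  bce_fake <- ad_mean(ad_softplus(d_fake))           # -mean log(1-sigma(d_fake))
  l_mm <- ad_neg(ad_add(bce_real, bce_fake))
  list(l_mm = l_mm,
       l_d = ad_smul(ad_add(bce_real, bce_fake), 0.5),
       l_g = ad_mean(ad_softplus(ad_neg(d_fake))))   # -mean log sigma(d_fake)
}
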