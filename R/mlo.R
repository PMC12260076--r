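# Three-level optimization: adversarial generator training, segmentation
# training on generated-plus-real data, and architecture selection by
# validation loss.
#
# Each iteration performs virtual one-step updates G -> G' (descent on the
# minimax objective) and S -> S' (descent on the mixed segmentation
# objective with G' plugged in), evaluates the validation loss at S', and
# differentiates it back to the architecture logits *through* both virtual
# steps.  The chain involves the cross second derivatives d2 L_gan / dA dG
# and d2 L_seg / dG' dS, which the autodiff engine provides exactly via
# double backward.  The architecture influences the hypergradient only
# through G' (the generated data are treated as a function of G' with the
# stage-II mixture coefficients held constant), so a zero generator rate
# severs the architecture gradient entirely.  Committed updates then use
# stateful optimizers, separate from the plain-gradient virtual steps.

#' Solver configuration for the trilevel optimizer
#'
#' Virtual steps use plain gradient updates with rates `eta_g`, `eta_h`,
#' `eta_s`; committed updates use stateful optimizers (RMSprop with
#' momentum for the segmenter, Adam for generator, discriminator and
#' architecture logits) with a plateau-based rate reduction on the
#' segmenter.  `gamma` trades off the real-data term against the generated
#' term in the segmentation objective.  Defaults target desk-scale runs
#' (tens of pairs, 32-64 px); reference full-scale settings use far smaller
#' rates (1e-5) and thousands of iterations.
#'
#' @param gamma Real-data trade-off, >= 0.
#' @param eta_g,eta_h,eta_s Virtual one-step rates (> 0 for learning; 0 is
#'   permitted and makes the corresponding dependence vanish).
#' @param eta_a Architecture (Adam) learning rate.
#' @param iterations Outer-loop iterations (>= 1).
#' @param warmup Adversarial warm-up: committed generator/discriminator
#'   updates run alone for this many iterations before the trilevel loop,
#'   so the segmenter never trains on images from an untrained generator.
#' @param batch_gan,batch_seg Mini-batch sizes for the adversarial and
#'   segmentation stages (capped at the dataset size).
#' @param synth_ratio Generated pairs per real training mask per step.
#' @param l1_weight Weight of an optional L1 reconstruction term added to
#'   the generator's adversarial objective (0 disables it, the default).
#'   The generation model follows the Pix2Pix conditional-GAN design, whose
#'   practical recipe couples the adversarial loss with an L1 term; the
#'   discriminator objective is unaffected.
#' @param hypergradient_mode `"exact_unrolled"` (default; the only mode
#'   used by the package's own validation) or `"first_order"`, a cheaper
#'   heuristic that detaches the virtual-step gradients.
#' @param metric Checkpoint-selection metric: `"dice"` or `"jaccard"`.
#' @param val_every Validation cadence in iterations; `NULL` means once per
#'   epoch (one pass over the training pairs).
#' @param optim Committed-optimizer settings (list; see Details source).
#' @param seed Master seed for batching, augmentation and initialization.
#' @return An `mlo_config` object.
#' @export
mlo_config <- function(gamma = 1, eta_g = 0.1, eta_h = 0.1, eta_s = 0.1,
                       eta_a = 0.01, iterations = 300L, warmup = 100L,
                       batch_gan = 4L, batch_seg = 4L, synth_ratio = 1,
                       l1_weight = 0,
                       hypergradient_mode = c("exact_unrolled", "first_order"),
                       metric = c("dice", "jaccard"), val_every = NULL,
                       optim = list(), seed = 1L) {
  hypergradient_mode <- match.arg(hypergradient_mode)
  metric <- match.arg(metric)
  stopifnot(gamma >= 0, eta_g >= 0, eta_h >= 0, eta_s >= 0, eta_a >= 0,
            iterations >= 1L, warmup >= 0L, l1_weight >= 0)
  defaults <- list(
    s_lr = 2e-3, s_momentum = 0.9, s_alpha = 0.99, s_wd = 1e-3,
    g_lr = 5e-3, g_betas = c(0.5, 0.999), g_wd = 1e-3,
    h_lr = 5e-3, h_betas = c(0.5, 0.999), h_wd = 1e-3,
    a_betas = c(0.5, 0.999), a_wd = 1e-5,
    plateau_patience = 20L, plateau_factor = 0.5, min_lr = 1e-4)
  optim <- utils::modifyList(defaults, optim)
  structure(list(gamma = gamma, eta_g = eta_g, eta_h = eta_h, eta_s = eta_s,
                 eta_a = eta_a, iterations = as.integer(iterations),
                 warmup = as.integer(warmup),
                 batch_gan = as.integer(batch_gan),
                 batch_seg = as.integer(batch_seg),
                 synth_ratio = synth_ratio, l1_weight = l1_weight,
                 hypergradient_mode = hypergradient_mode,
                 metric = metric, val_every = val_every,
                 optim = optim, seed = as.integer(seed)),
            class = "mlo_config")
}

## ---- committed optimizers -------------------------------------------------

opt_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(state, params, grads, lr, betas = c(0.9, 0.999),
                      wd = 0, eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1L]; b2 <- betas[2L]
  for (i in seq_along(params)) {
    g <- grads[[i]] + wd * params[[i]]
    state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * g
    state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * g^2
    mhat <- state$m[[i]] / (1 - b1^state$t)
    vhat <- state$v[[i]] / (1 - b2^state$t)
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

rmsprop_step <- function(state, params, grads, lr, momentum = 0.9,
                         alpha = 0.99, wd = 0, eps = 1e-8) {
  for (i in seq_along(params)) {
    g <- grads[[i]] + wd * params[[i]]
    state$v[[i]] <- alpha * state$v[[i]] + (1 - alpha) * g^2
    state$m[[i]] <- momentum * state$m[[i]] + g / (sqrt(state$v[[i]]) + eps)
    params[[i]] <- params[[i]] - lr * state$m[[i]]
  }
  list(params = params, state = state)
}

## ---- generic virtual step -------------------------------------------------

#' One differentiable gradient step on an arbitrary scalar objective
#'
#' The primitive behind the solver's virtual updates: given parameter
#' values and a loss builder, performs `p' = p -+ eta * dL/dp` while keeping
#' `p'` a differentiable function of everything the loss depends on.
#'
#' @param params Named list of numeric arrays.
#' @param loss_fn Function taking the list of parameter nodes and returning
#'   a scalar loss node.
#' @param eta Step size (>= 0); `eta = 0` returns the parameters unchanged.
#' @param ascent Take an ascent step instead of descent.
#' @return List with `params` (updated values), `grads` (numeric), `loss`
#'   (numeric), and the graph nodes (`param_nodes`, `updated_nodes`,
#'   `loss_node`) for further differentiation.
#' @export
virtual_sgd_step <- function(params, loss_fn, eta, ascent = FALSE) {
  pn <- leaf_params(params)
  loss <- loss_fn(pn)
  g <- ad_grad(loss, pn)
  if (!all(vapply(g, function(x) all(is.finite(x$value)), TRUE))) {
    stop("non-finite gradients in virtual step")
  }
  upd <- step_params(pn, g, if (ascent) -eta else eta)
  list(params = values_of(upd), grads = values_of(g), loss = loss$value,
       param_nodes = pn, updated_nodes = upd, loss_node = loss)
}

## ---- the full pipeline graph ----------------------------------------------

softmax_graph <- function(logits_node) {
  lv <- logits_node$value
  m <- apply(lv, 2L, max)
  Zc <- ad_sub(logits_node, ad_const(matrix(m, nrow(lv), ncol(lv), byrow = TRUE)))
  E <- ad_exp(Zc)
  ad_div(E, ad_rowbcast(ad_colsums(E), nrow(lv)))
}

# Builds the full three-stage graph.  `stage2_alphas` is the constant copy
# of the mixture coefficients used when generating the synthetic training
# set (defaults to the current softmax of `logits_value`); the architecture
# gradient runs only through the stage-I GAN loss, matching the stated
# hypergradient chain.
mlo_pipeline <- function(gen, disc, seg, logits_value, gan_batch, aug_masks,
                         tr_batch, val_batch, config,
                         stage2_alphas = NULL) {
  L <- gen$config$label_count
  first_order <- identical(config$hypergradient_mode, "first_order")

  G_l <- leaf_params(gen$params)
  H_l <- leaf_params(disc$params)
  S_l <- leaf_params(seg$params)
  log_l <- ad_leaf(logits_value, requires_grad = TRUE)
  alphas <- softmax_graph(log_l)

  ## stage I: adversarial objective on the role-swapped view
  B1 <- length(gan_batch)
  gan_masks <- lapply(gan_batch, `[[`, "mask")
  m1h <- ad_const(onehot_masks(gan_masks, L))
  real_img <- ad_const(stack_images(lapply(gan_batch, `[[`, "image")))
  fake_img <- gen_forward_graph(gen, G_l, alphas, m1h, B1)
  cond <- if (disc$config$conditional) m1h else NULL
  d_real <- disc_forward_graph(disc, H_l, real_img, cond, B1)
  d_fake <- disc_forward_graph(disc, H_l, fake_img, cond, B1)
  gl <- gan_graph_losses(d_real, d_fake)
  l1w <- config$l1_weight %||% 0
  # the reconstruction term involves only G, so one backward of the
  # combined objective yields d(gen_obj)/dG and d(l_mm)/dH exactly
  gen_obj <- if (l1w > 0) {
    ad_add(gl$l_mm, ad_smul(ad_mean(ad_abs(ad_sub(fake_img, real_img))), l1w))
  } else gl$l_mm

  nG <- length(G_l)
  gGH <- ad_grad(gen_obj, c(G_l, H_l))
  gG <- gGH[seq_len(nG)]
  gH <- gGH[nG + seq_along(H_l)]
  if (first_order) gG <- lapply(gG, function(n) ad_const(n$value))
  Gp <- step_params(G_l, gG, config$eta_g)          # G': descent step
  Hp <- step_params(H_l, gH, -config$eta_h)         # H': ascent step

  ## stage II: synthesize and take the virtual segmenter step
  B2 <- length(aug_masks)
  a2 <- if (is.null(stage2_alphas)) ad_const(alphas$value) else ad_const(stage2_alphas)
  if (first_order) a2 <- alphas   # direct path is all that survives
  m2h <- ad_const(onehot_masks(aug_masks, L))
  synth_img <- gen_forward_graph(gen, Gp, a2, m2h, B2)
  sc_gen <- seg_forward_graph(seg, S_l, synth_img, B2)
  l_seg_gen <- nn_softmax_ce(sc_gen, unlist(lapply(aug_masks, as.vector)))

  B3 <- length(tr_batch)
  sc_real <- seg_forward_graph(seg, S_l,
                               ad_const(stack_images(lapply(tr_batch, `[[`, "image"))),
                               B3)
  l_seg_real <- nn_softmax_ce(sc_real,
                              unlist(lapply(tr_batch, function(p) as.vector(p$mask))))
  L_s <- ad_add(l_seg_gen, ad_smul(l_seg_real, config$gamma))

  gS <- ad_grad(L_s, S_l)
  if (first_order) gS <- lapply(gS, function(n) ad_const(n$value))
  Sp <- step_params(S_l, gS, config$eta_s)          # S': descent step

  ## stage III: validation loss at S'
  Bv <- length(val_batch)
  sc_val <- seg_forward_graph(seg, Sp,
                              ad_const(stack_images(lapply(val_batch, `[[`, "image"))),
                              Bv)
  L_val <- nn_softmax_ce(sc_val,
                         unlist(lapply(val_batch, function(p) as.vector(p$mask))))

  list(log_l = log_l, alphas = alphas,
       G_l = G_l, H_l = H_l, S_l = S_l,
       gan = gl, gG = gG, gH = gH, Gp = Gp, Hp = Hp,
       l_seg_gen = l_seg_gen, l_seg_real = l_seg_real, L_s = L_s,
       gS = gS, Sp = Sp, L_val = L_val,
       # objective differentiated w.r.t. the logits: the validation loss in
       # exact mode; in first-order mode the surviving direct path is the
       # stage-II training loss through the mixture coefficients
       arch_obj = if (first_order) L_s else L_val)
}

#' Virtual one-step adversarial update
#'
#' Performs `G' = G - eta_g * dL_gan/dG` and `H' = H + eta_h * dL_gan/dH`
#' on the minimax objective evaluated on a batch of role-swapped pairs,
#' keeping the functional dependence of `G'` on the architecture intact in
#' the returned nodes.
#'
#' @param generator,arch,discriminator Models as built by
#'   [build_searchable_generator()] / [build_discriminator()].
#' @param gan_batch Non-empty list of pairs (`mask`, `image`).
#' @param eta_g,eta_h Step sizes.
#' @return List with updated parameter values `G_prime`, `H_prime`, the
#'   gradients, the loss value, and the underlying graph nodes.
#' @export
virtual_gan_step <- function(generator, discriminator, arch, gan_batch,
                             eta_g, eta_h) {
  if (length(gan_batch) == 0L) stop("empty adversarial batch")
  L <- generator$config$label_count
  G_l <- leaf_params(generator$params)
  H_l <- leaf_params(discriminator$params)
  B <- length(gan_batch)
  m1h <- ad_const(onehot_masks(lapply(gan_batch, `[[`, "mask"), L))
  real_img <- ad_const(stack_images(lapply(gan_batch, `[[`, "image")))
  an <- ad_leaf(alphas_of(arch), requires_grad = TRUE)
  fake <- gen_forward_graph(generator, G_l, an, m1h, B)
  cond <- if (discriminator$config$conditional) m1h else NULL
  gl <- gan_graph_losses(disc_forward_graph(discriminator, H_l, real_img, cond, B),
                         disc_forward_graph(discriminator, H_l, fake, cond, B))
  gGH <- ad_grad(gl$l_mm, c(G_l, H_l))
  if (!all(vapply(gGH, function(x) all(is.finite(x$value)), TRUE))) {
    stop("non-finite adversarial gradients")
  }
  gG <- gGH[seq_along(G_l)]
  gH <- gGH[length(G_l) + seq_along(H_l)]
  Gp <- step_params(G_l, gG, eta_g)
  Hp <- step_params(H_l, gH, -eta_h)
  list(G_prime = values_of(Gp), H_prime = values_of(Hp),
       grad_G = values_of(gG), grad_H = values_of(gH),
       l_gan = gl$l_mm$value,
       nodes = list(G = G_l, H = H_l, alphas = an, Gp = Gp, Hp = Hp, gan = gl))
}

#' Generate a synthetic training set from augmented real masks
#'
#' For each requested synthetic pair a real training mask is augmented and
#' the generator synthesizes the matching image, yielding pairs of
#' generated image and augmented mask.  Deterministic given the seed.
#'
#' @param generator,arch The mask-to-image generator and its selection
#'   weights.
#' @param train_masks List of integer masks from the training split.
#' @param aug_config An [augment_config()]; `NULL` disables augmentation.
#' @param seed Integer seed.
#' @param count Number of pairs to generate (default one per mask).
#' @return A [seg_dataset()] of generated pairs.
#' @export
synthesize_training_set <- function(generator, arch, train_masks,
                                    aug_config = augment_config(),
                                    seed = 1L, count = NULL) {
  n <- count %||% length(train_masks)
  idx <- rep_len(seq_along(train_masks), n)
  aug <- lapply(seq_len(n), function(i) {
    m <- train_masks[[idx[i]]]
    if (is.null(aug_config)) m else augment_mask(m, aug_config, seed = derive_seed(seed, i))
  })
  imgs <- if (n > 0L) generate_image(generator, arch, aug) else list()
  pairs <- lapply(seq_len(n), function(i) {
    mask_image_pair(imgs[[i]], aug[[i]], id = sprintf("synth-%03d", i),
                    label_count = generator$config$label_count)
  })
  seg_dataset(pairs, split = "train", label_count = generator$config$label_count,
              provenance = list(generator = "synthesized", seed = seed))
}

#' Virtual one-step segmenter update
#'
#' `S' = S - eta_s * dS [ L_seg(S, generated) + gamma * L_seg(S, real) ]`.
#'
#' @param segmenter A [build_unet()] model.
#' @param synth_pairs,real_pairs Lists of pairs (generated and real).
#' @param gamma Real-data trade-off.
#' @param eta_s Step size.
#' @return List with `S_prime` values, `grads`, `loss` and graph nodes.
#' @export
virtual_seg_step <- function(segmenter, synth_pairs, real_pairs, gamma, eta_s) {
  if (length(synth_pairs) == 0L && gamma == 0) stop("nothing to train on")
  loss_fn <- function(S_l) {
    total <- NULL
    if (length(synth_pairs) > 0L) {
      sc <- seg_forward_graph(segmenter, S_l,
                              ad_const(stack_images(lapply(synth_pairs, `[[`, "image"))),
                              length(synth_pairs))
      total <- nn_softmax_ce(sc, unlist(lapply(synth_pairs,
                                               function(p) as.vector(p$mask))))
    }
    if (gamma > 0 && length(real_pairs) > 0L) {
      sc <- seg_forward_graph(segmenter, S_l,
                              ad_const(stack_images(lapply(real_pairs, `[[`, "image"))),
                              length(real_pairs))
      lr <- ad_smul(nn_softmax_ce(sc, unlist(lapply(real_pairs,
                                                    function(p) as.vector(p$mask)))),
                    gamma)
      total <- if (is.null(total)) lr else ad_add(total, lr)
    }
    total
  }
  st <- virtual_sgd_step(segmenter$params, loss_fn, eta_s)
  list(S_prime = st$params, grads = st$grads, loss = st$loss,
       nodes = st)
}

#' Exact unrolled architecture gradient
#'
#' Computes the gradient of the validation segmentation loss with respect
#' to the architecture logits through both virtual steps: the product of
#' dG'/dA (a cross second derivative of the adversarial loss), dS'/dG'
#' (a cross second derivative of the mixed segmentation objective) and the
#' validation-loss gradient at S'.  With `eta_g = 0` or `eta_s = 0` the
#' result is identically zero.
#'
#' @param generator,discriminator,segmenter,arch The four models.
#' @param batches List with components `gan` (pairs), `aug_masks`
#'   (augmented masks for synthesis), `train` (pairs) and `val` (pairs).
#' @param config An [mlo_config()].
#' @return Numeric matrix of the same shape as `arch$logits`.
#' @export
architecture_gradient <- function(generator, discriminator, segmenter, arch,
                                  batches, config) {
  pl <- mlo_pipeline(generator, discriminator, segmenter, arch$logits,
                     batches$gan, batches$aug_masks, batches$train,
                     batches$val, config)
  g <- ad_grad(pl$arch_obj, pl$log_l)
  structure(g$value, dim = dim(arch$logits))
}

## ---- training loops -------------------------------------------------------

sample_batch <- function(pairs, size, seed) {
  n <- length(pairs)
  size <- min(size, n)
  idx <- with_seed(seed, sample.int(n, size))
  pairs[idx]
}

validate_metric <- function(seg, val_pairs, metric) {
  fn <- metric_fn(metric)
  preds <- predict_mask(seg, lapply(val_pairs, `[[`, "image"))
  mean(vapply(seq_along(val_pairs),
              function(i) fn(preds[[i]], val_pairs[[i]]$mask), numeric(1)))
}

new_fit <- function(method, gen, disc, seg, arch, best, history, val_history,
                    config) {
  structure(list(method = method, generator = gen, discriminator = disc,
                 segmenter = seg, arch = arch, best = best,
                 history = history, val_history = val_history,
                 config = config),
            class = "genaug_fit")
}

#' @export
print.genaug_fit <- function(x, ...) {
  cat("<genaug_fit method='", x$method, "': ", nrow(x$history),
      " iterations, best val ", x$config$metric, " = ",
      round(x$best$metric, 4), " @ iter ", x$best$iteration, ">\n", sep = "")
  invisible(x)
}

#' Segmenter at the best-validation checkpoint
#'
#' @param fit A fitted object from [train_genseg()], [train_separate()] or
#'   [train_vanilla()].
#' @return A `segmenter` with the checkpointed weights.
#' @export
best_segmenter <- function(fit) {
  seg <- fit$segmenter
  seg$params <- fit$best$seg_params
  seg
}

default_models <- function(D_tr, config, model_opts) {
  mo <- utils::modifyList(list(
    depth = 2L, gen_base_width = 4L, disc_base_width = 4L,
    seg_base_width = 4L, skip = TRUE, conditional = TRUE,
    channels = 1L, backbone = "unet",
    aug = augment_config()), model_opts)
  size <- nrow(D_tr$pairs[[1L]]$mask)
  L <- D_tr$label_count
  ga <- build_searchable_generator(size, channels = mo$channels, depth = mo$depth,
                                   base_width = mo$gen_base_width, skip = mo$skip,
                                   label_count = L, seed = derive_seed(config$seed, 11))
  disc <- build_discriminator(size, channels = mo$channels, label_count = L,
                              base_width = mo$disc_base_width,
                              conditional = mo$conditional,
                              seed = derive_seed(config$seed, 12))
  seg <- get_backbone(mo$backbone)(size, channels = mo$channels, label_count = L,
                                   base_width = mo$seg_base_width, depth = mo$depth,
                                   seed = derive_seed(config$seed, 13))
  list(gen = ga$generator, arch = ga$arch, disc = disc, seg = seg, opts = mo)
}

# one committed adversarial update (no trilevel machinery); used by the
# warm-up phase and by the separate baseline's first phase
gan_only_update <- function(gen, disc, alphas_const, gan_batch, opt_g, opt_h,
                            config) {
  L <- gen$config$label_count
  B <- length(gan_batch)
  G_l <- leaf_params(gen$params)
  H_l <- leaf_params(disc$params)
  m1h <- ad_const(onehot_masks(lapply(gan_batch, `[[`, "mask"), L))
  real_img <- ad_const(stack_images(lapply(gan_batch, `[[`, "image")))
  fake <- gen_forward_graph(gen, G_l, alphas_const, m1h, B)
  cond <- if (disc$config$conditional) m1h else NULL
  gl <- gan_graph_losses(disc_forward_graph(disc, H_l, real_img, cond, B),
                         disc_forward_graph(disc, H_l, fake, cond, B))
  l1w <- config$l1_weight %||% 0
  gen_obj <- if (l1w > 0) {
    ad_add(gl$l_mm, ad_smul(ad_mean(ad_abs(ad_sub(fake, real_img))), l1w))
  } else gl$l_mm
  gGH <- ad_grad(gen_obj, c(G_l, H_l))
  gGc <- values_of(gGH[seq_along(G_l)])
  gHc <- lapply(gGH[length(G_l) + seq_along(H_l)], function(n) -n$value / 2)
  upd <- adam_step(opt_g, gen$params, gGc, lr = config$optim$g_lr,
                   betas = config$optim$g_betas, wd = config$optim$g_wd)
  gen$params <- upd$params; opt_g <- upd$state
  upd <- adam_step(opt_h, disc$params, gHc, lr = config$optim$h_lr,
                   betas = config$optim$h_betas, wd = config$optim$h_wd)
  disc$params <- upd$params; opt_h <- upd$state
  list(gen = gen, disc = disc, opt_g = opt_g, opt_h = opt_h, losses = gl)
}

check_splits <- function(D_tr, D_val) {
  if (!inherits(D_tr, "seg_dataset") || length(D_tr) < 1L) {
    stop("training split must be a non-empty seg_dataset")
  }
  if (!inherits(D_val, "seg_dataset") || length(D_val) < 1L) {
    stop("validation split must be a non-empty seg_dataset")
  }
}

plateau_update <- function(sched, metric, optcfg) {
  if (metric > sched$best + 1e-12) {
    sched$best <- metric
    sched$bad <- 0L
  } else {
    sched$bad <- sched$bad + 1L
    if (sched$bad > optcfg$plateau_patience) {
      sched$lr <- max(sched$lr * optcfg$plateau_factor, optcfg$min_lr)
      sched$bad <- 0L
    }
  }
  sched
}

#' Train the full end-to-end generative-augmentation model
#'
#' Runs the configured number of trilevel iterations.  Each iteration: (i)
#' virtual adversarial step on a role-swapped batch; (ii) mask
#' augmentation and synthesis of a generated batch with the stepped
#' generator; (iii) virtual segmenter step on generated + real data; (iv)
#' architecture update from the exact unrolled validation-loss gradient;
#' then committed optimizer updates of generator, discriminator and
#' segmenter.  Validation runs on a fixed cadence and the returned
#' checkpoint maximizes the validation metric.
#'
#' @param D_tr,D_val Non-empty training and validation [seg_dataset()]s.
#' @param config An [mlo_config()].
#' @param model_opts Optional list overriding model hyperparameters
#'   (`depth`, `gen_base_width`, `disc_base_width`, `seg_base_width`,
#'   `skip`, `conditional`, `backbone`, `aug`).
#' @return A `genaug_fit` object; see [best_segmenter()], [generics::tidy()]
#'   and [generics::glance()] methods.
#' @export
train_genseg <- function(D_tr, D_val, config = mlo_config(),
                         model_opts = list()) {
  check_splits(D_tr, D_val)
  ms <- default_models(D_tr, config, model_opts)
  gen <- ms$gen; disc <- ms$disc; seg <- ms$seg; arch <- ms$arch
  aug <- ms$opts$aug
  val_pairs <- D_val$pairs
  n_tr <- length(D_tr)
  epoch_len <- max(1L, ceiling(n_tr / config$batch_seg))
  val_every <- config$val_every %||% epoch_len

  opt_g <- opt_init(gen$params)
  opt_h <- opt_init(disc$params)
  opt_s <- opt_init(seg$params)
  opt_a <- opt_init(list(logits = arch$logits))
  sched <- list(lr = config$optim$s_lr, best = -Inf, bad = 0L)

  best <- list(metric = -Inf, iteration = 0L, seg_params = seg$params)
  hist <- vector("list", config$iterations)
  vhist <- list()

  ## adversarial warm-up: bring the generator to a usable operating point
  ## before any synthetic image reaches the segmenter
  if (config$warmup > 0L) {
    a0 <- ad_const(alphas_of(arch))
    for (wit in seq_len(config$warmup)) {
      gb <- sample_batch(D_tr$pairs, config$batch_gan,
                         derive_seed(config$seed, 700000L + wit))
      gu <- gan_only_update(gen, disc, a0, gb, opt_g, opt_h, config)
      gen <- gu$gen; disc <- gu$disc; opt_g <- gu$opt_g; opt_h <- gu$opt_h
    }
  }

  for (it in seq_len(config$iterations)) {
    gan_batch <- sample_batch(D_tr$pairs, config$batch_gan,
                              derive_seed(config$seed, it * 4L))
    tr_batch <- sample_batch(D_tr$pairs, config$batch_seg,
                             derive_seed(config$seed, it * 4L + 1L))
    n_synth <- max(1L, round(config$synth_ratio * length(tr_batch)))
    src <- rep_len(seq_along(tr_batch), n_synth)
    aug_masks <- lapply(seq_len(n_synth), function(i) {
      m <- tr_batch[[src[i]]]$mask
      if (is.null(aug)) m else {
        augment_mask(m, aug, seed = derive_seed(config$seed, it * 4L + 2L) + i)
      }
    })

    pl <- mlo_pipeline(gen, disc, seg, arch$logits, gan_batch, aug_masks,
                       tr_batch, val_pairs, config)
    if (!is.finite(pl$L_val$value) || !is.finite(pl$L_s$value)) {
      stop("non-finite loss at iteration ", it, " (l_seg = ", pl$L_s$value,
           ", l_val = ", pl$L_val$value, ")")
    }

    ## architecture update from the unrolled hypergradient
    if (config$eta_a > 0) {
      gA <- ad_grad(pl$arch_obj, pl$log_l)$value
      upd <- adam_step(opt_a, list(logits = arch$logits), list(logits = gA),
                       lr = config$eta_a, betas = config$optim$a_betas,
                       wd = config$optim$a_wd)
      arch$logits <- upd$params$logits
      opt_a <- upd$state
    }

    ## committed updates with stateful optimizers; the generator descends
    ## the same minimax objective as its virtual step, and the
    ## discriminator's BCE gradient is -1/2 times its ascent gradient,
    ## so both reuse the stage-I backward
    gGc <- values_of(pl$gG)
    upd <- adam_step(opt_g, gen$params, gGc, lr = config$optim$g_lr,
                     betas = config$optim$g_betas, wd = config$optim$g_wd)
    gen$params <- upd$params; opt_g <- upd$state

    gHc <- lapply(pl$gH, function(n) -n$value / 2)      # grad of l_d
    upd <- adam_step(opt_h, disc$params, gHc, lr = config$optim$h_lr,
                     betas = config$optim$h_betas, wd = config$optim$h_wd)
    disc$params <- upd$params; opt_h <- upd$state

    upd <- rmsprop_step(opt_s, seg$params, values_of(pl$gS), lr = sched$lr,
                        momentum = config$optim$s_momentum,
                        alpha = config$optim$s_alpha, wd = config$optim$s_wd)
    seg$params <- upd$params; opt_s <- upd$state

    hist[[it]] <- tibble::tibble(
      iteration = it, l_gan = pl$gan$l_mm$value, l_d = pl$gan$l_d$value,
      l_g = pl$gan$l_g$value, l_seg_gen = pl$l_seg_gen$value,
      l_seg_real = pl$l_seg_real$value, l_val = pl$L_val$value,
      s_lr = sched$lr)

    if (it %% val_every == 0L || it == config$iterations) {
      vm <- validate_metric(seg, val_pairs, config$metric)
      vhist[[length(vhist) + 1L]] <- tibble::tibble(iteration = it, metric = vm)
      if (vm > best$metric) {
        best <- list(metric = vm, iteration = it, seg_params = seg$params)
      }
      sched <- plateau_update(sched, vm, config$optim)
    }
  }

  new_fit("genseg", gen, disc, seg, arch, best,
          dplyr::bind_rows(hist), dplyr::bind_rows(vhist), config)
}

#' Train the non-end-to-end "separate" baseline
#'
#' Phase 1 trains the adversarial generator alone on the role-swapped
#' training pairs (architecture logits frozen at initialization).  Phase 2
#' freezes the generator and its architecture, regenerates a synthetic set
#' once per epoch, and trains the segmenter on generated + `gamma` * real
#' data.  No architecture updates ever occur.
#'
#' @inheritParams train_genseg
#' @return A `genaug_fit` with `method = "separate"`.
#' @export
train_separate <- function(D_tr, D_val, config = mlo_config(),
                           model_opts = list()) {
  check_splits(D_tr, D_val)
  ms <- default_models(D_tr, config, model_opts)
  gen <- ms$gen; disc <- ms$disc; seg <- ms$seg; arch <- ms$arch
  aug <- ms$opts$aug
  val_pairs <- D_val$pairs
  n_tr <- length(D_tr)
  epoch_len <- max(1L, ceiling(n_tr / config$batch_seg))
  val_every <- config$val_every %||% epoch_len
  alphas_const <- ad_const(alphas_of(arch))
  L <- gen$config$label_count

  opt_g <- opt_init(gen$params)
  opt_h <- opt_init(disc$params)
  hist <- list()

  ## phase 1: adversarial training only (warm-up plus budget)
  n_gan <- config$warmup + config$iterations
  for (it in seq_len(n_gan)) {
    gan_batch <- sample_batch(D_tr$pairs, config$batch_gan,
                              derive_seed(config$seed, it * 4L))
    gu <- gan_only_update(gen, disc, alphas_const, gan_batch, opt_g, opt_h,
                          config)
    gen <- gu$gen; disc <- gu$disc; opt_g <- gu$opt_g; opt_h <- gu$opt_h
    gl <- gu$losses
    hist[[length(hist) + 1L]] <- tibble::tibble(
      iteration = it, phase = "gan", l_gan = gl$l_mm$value,
      l_d = gl$l_d$value, l_g = gl$l_g$value,
      l_seg_gen = NA_real_, l_seg_real = NA_real_, s_lr = NA_real_)
  }

  ## phase 2: frozen generator, segmenter training
  opt_s <- opt_init(seg$params)
  sched <- list(lr = config$optim$s_lr, best = -Inf, bad = 0L)
  best <- list(metric = -Inf, iteration = 0L, seg_params = seg$params)
  vhist <- list()
  synth <- NULL
  tr_masks <- ds_masks(D_tr)

  for (it in seq_len(config$iterations)) {
    if (is.null(synth) || (it - 1L) %% epoch_len == 0L) {
      synth <- synthesize_training_set(gen, arch, tr_masks, aug,
                                       seed = derive_seed(config$seed, 9000L + it))
    }
    tr_batch <- sample_batch(D_tr$pairs, config$batch_seg,
                             derive_seed(config$seed, it * 4L + 1L))
    sy_batch <- sample_batch(synth$pairs, config$batch_seg,
                             derive_seed(config$seed, it * 4L + 3L))
    st <- virtual_seg_step(seg, sy_batch, tr_batch, config$gamma, 0)
    upd <- rmsprop_step(opt_s, seg$params, st$grads, lr = sched$lr,
                        momentum = config$optim$s_momentum,
                        alpha = config$optim$s_alpha, wd = config$optim$s_wd)
    seg$params <- upd$params; opt_s <- upd$state
    hist[[length(hist) + 1L]] <- tibble::tibble(
      iteration = it, phase = "seg", l_gan = NA_real_, l_d = NA_real_,
      l_g = NA_real_, l_seg_gen = st$loss, l_seg_real = NA_real_,
      s_lr = sched$lr)
    if (it %% val_every == 0L || it == config$iterations) {
      vm <- validate_metric(seg, val_pairs, config$metric)
      vhist[[length(vhist) + 1L]] <- tibble::tibble(iteration = it, metric = vm)
      if (vm > best$metric) {
        best <- list(metric = vm, iteration = it, seg_params = seg$params)
      }
      sched <- plateau_update(sched, vm, config$optim)
    }
  }

  new_fit("separate", gen, disc, seg, arch, best,
          dplyr::bind_rows(hist), dplyr::bind_rows(vhist), config)
}

#' Train the vanilla no-augmentation baseline
#'
#' Same backbone, optimizer, schedule and checkpoint rule, trained on the
#' real pairs only (no generated data).
#'
#' @inheritParams train_genseg
#' @return A `genaug_fit` with `method = "vanilla"`.
#' @export
train_vanilla <- function(D_tr, D_val, config = mlo_config(),
                          model_opts = list()) {
  check_splits(D_tr, D_val)
  ms <- default_models(D_tr, config, model_opts)
  seg <- ms$seg
  val_pairs <- D_val$pairs
  epoch_len <- max(1L, ceiling(length(D_tr) / config$batch_seg))
  val_every <- config$val_every %||% epoch_len
  opt_s <- opt_init(seg$params)
  sched <- list(lr = config$optim$s_lr, best = -Inf, bad = 0L)
  best <- list(metric = -Inf, iteration = 0L, seg_params = seg$params)
  hist <- vector("list", config$iterations)
  vhist <- list()

  for (it in seq_len(config$iterations)) {
    tr_batch <- sample_batch(D_tr$pairs, config$batch_seg,
                             derive_seed(config$seed, it * 4L + 1L))
    st <- virtual_seg_step(seg, list(), tr_batch, gamma = 1, eta_s = 0)
    upd <- rmsprop_step(opt_s, seg$params, st$grads, lr = sched$lr,
                        momentum = config$optim$s_momentum,
                        alpha = config$optim$s_alpha, wd = config$optim$s_wd)
    seg$params <- upd$params; opt_s <- upd$state
    hist[[it]] <- tibble::tibble(iteration = it, l_seg_real = st$loss,
                                 s_lr = sched$lr)
    if (it %% val_every == 0L || it == config$iterations) {
      vm <- validate_metric(seg, val_pairs, config$metric)
      vhist[[length(vhist) + 1L]] <- tibble::tibble(iteration = it, metric = vm)
      if (vm > best$metric) {
        best <- list(metric = vm, iteration = it, seg_params = seg$params)
      }
      sched <- plateau_update(sched, vm, config$optim)
    }
  }

  new_fit("vanilla", ms$gen, ms$disc, seg, ms$arch, best,
          dplyr::bind_rows(hist), dplyr::bind_rows(vhist), config)
}

#' One full trilevel iteration (exposed for inspection and testing)
#'
#' Applies the four updates of one outer-loop step to an explicit state and
#' returns the new state together with the recorded losses.
#'
#' @param state List with components `gen`, `disc`, `seg`, `arch`, and
#'   optimizer states as produced by the training loop (or a fresh state
#'   from the model builders with `opt_* = NULL`).
#' @param batches List with `gan`, `aug_masks`, `train`, `val`.
#' @param config An [mlo_config()].
#' @return Updated state; losses in `state$last`.
#' @export
mlo_iteration <- function(state, batches, config) {
  gen <- state$gen; disc <- state$disc; seg <- state$seg; arch <- state$arch
  state$opt_g <- state$opt_g %||% opt_init(gen$params)
  state$opt_h <- state$opt_h %||% opt_init(disc$params)
  state$opt_s <- state$opt_s %||% opt_init(seg$params)
  state$opt_a <- state$opt_a %||% opt_init(list(logits = arch$logits))

  pl <- mlo_pipeline(gen, disc, seg, arch$logits, batches$gan,
                     batches$aug_masks, batches$train, batches$val, config)
  if (!is.finite(pl$L_val$value)) stop("non-finite validation loss")

  if (config$eta_a > 0) {
    gA <- ad_grad(pl$arch_obj, pl$log_l)$value
    upd <- adam_step(state$opt_a, list(logits = arch$logits),
                     list(logits = gA), lr = config$eta_a,
                     betas = config$optim$a_betas, wd = config$optim$a_wd)
    arch$logits <- upd$params$logits
    state$opt_a <- upd$state
  }
  gGc <- values_of(pl$gG)
  upd <- adam_step(state$opt_g, gen$params, gGc, lr = config$optim$g_lr,
                   betas = config$optim$g_betas, wd = config$optim$g_wd)
  gen$params <- upd$params; state$opt_g <- upd$state
  gHc <- lapply(pl$gH, function(n) -n$value / 2)
  upd <- adam_step(state$opt_h, disc$params, gHc, lr = config$optim$h_lr,
                   betas = config$optim$h_betas, wd = config$optim$h_wd)
  disc$params <- upd$params; state$opt_h <- upd$state
  upd <- rmsprop_step(state$opt_s, seg$params, values_of(pl$gS),
                      lr = config$optim$s_lr,
                      momentum = config$optim$s_momentum,
                      alpha = config$optim$s_alpha, wd = config$optim$s_wd)
  seg$params <- upd$params; state$opt_s <- upd$state

  state$gen <- gen; state$disc <- disc; state$seg <- seg; state$arch <- arch
  state$last <- list(l_gan = pl$gan$l_mm$value, l_d = pl$gan$l_d$value,
                     l_g = pl$gan$l_g$value, l_seg = pl$L_s$value,
                     l_val = pl$L_val$value)
  state
}
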