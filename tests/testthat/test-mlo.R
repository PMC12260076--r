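# The trilevel solver: virtual one-step updates, the synthetic training
# set, the exact unrolled architecture gradient, and the training loops.

test_that("virtual steps match closed forms on scalar quadratics", {
  # L(G) = (G - a)^2 with a = 0: one step from G = 1 at eta 0.1 gives 0.8
  loss <- function(p) {
    d <- genaug:::ad_sub(p$g, genaug:::ad_const(0))
    genaug:::ad_mul(d, d)
  }
  st <- virtual_sgd_step(list(g = 1), loss, eta = 0.1)
  expect_equal(st$params$g, 0.8, tolerance = 1e-15)
  expect_equal(st$grads$g, 2, tolerance = 1e-15)

  same <- virtual_sgd_step(list(g = 1), loss, eta = 0)
  expect_identical(same$params$g, 1)

  up <- virtual_sgd_step(list(g = 1), loss, eta = 0.1, ascent = TRUE)
  expect_equal(up$params$g, 1.2, tolerance = 1e-15)
})

test_that("virtual adversarial step matches finite differences on tiny nets", {
  s <- tiny_mlo_setup()
  st <- virtual_gan_step(s$gen, s$disc, s$arch, s$batches$gan,
                         eta_g = 0.1, eta_h = 0.1)
  # eta = 0 leaves parameters unchanged
  id <- virtual_gan_step(s$gen, s$disc, s$arch, s$batches$gan, 0, 0)
  expect_equal(id$G_prime, s$gen$params, tolerance = 1e-15)
  expect_equal(id$H_prime, s$disc$params, tolerance = 1e-15)

  # central-difference oracle on a few generator coordinates
  lval <- function(params) {
    gen2 <- s$gen; gen2$params <- params
    vs <- virtual_gan_step(gen2, s$disc, s$arch, s$batches$gan, 0, 0)
    vs$l_gan
  }
  h <- 1e-6
  for (nm in c("enc1.b1.w", "dec1.b2.w", "head.w")) {
    i <- 1L
    pp <- s$gen$params; pm <- s$gen$params
    pp[[nm]][i] <- pp[[nm]][i] + h
    pm[[nm]][i] <- pm[[nm]][i] - h
    fd <- (lval(pp) - lval(pm)) / (2 * h)
    got <- st$grad_G[[nm]][i]
    expect_lt(abs(got - fd) / max(abs(fd), 1e-8), 1e-6)
    expect_equal(st$G_prime[[nm]][i], s$gen$params[[nm]][i] - 0.1 * got,
                 tolerance = 1e-12)
  }
})

test_that("the synthetic set pairs generated images with augmented masks", {
  s <- tiny_mlo_setup()
  masks <- lapply(s$batches$train, `[[`, "mask")
  aug <- augment_config()

  d1 <- synthesize_training_set(s$gen, s$arch, masks, aug, seed = 5)
  d2 <- synthesize_training_set(s$gen, s$arch, masks, aug, seed = 5)
  expect_length(d1$pairs, length(masks))
  expect_identical(lapply(d1$pairs, `[[`, "image"),
                   lapply(d2$pairs, `[[`, "image"))
  expect_identical(lapply(d1$pairs, `[[`, "mask"),
                   lapply(d2$pairs, `[[`, "mask"))

  # no augmentation: masks of the generated set equal the real masks
  plain <- synthesize_training_set(s$gen, s$arch, masks, aug_config = NULL,
                                   seed = 1)
  expect_identical(lapply(plain$pairs, `[[`, "mask"), masks)
  # and each generated image is the generator's output for that mask
  expect_equal(plain$pairs[[1]]$image,
               generate_image(s$gen, s$arch, masks[[1]]), tolerance = 1e-12)
})

test_that("the virtual segmenter step follows the mixed objective", {
  s <- tiny_mlo_setup()
  synth <- synthesize_training_set(s$gen, s$arch,
                                   lapply(s$batches$train, `[[`, "mask"),
                                   aug_config = NULL, seed = 2)$pairs
  real <- s$batches$train

  same <- virtual_seg_step(s$seg, synth, real, gamma = 1, eta_s = 0)
  expect_equal(same$S_prime, s$seg$params, tolerance = 1e-15)

  # gamma = 0: the step cannot depend on the real data
  a <- virtual_seg_step(s$seg, synth, real, gamma = 0, eta_s = 0.1)
  b <- virtual_seg_step(s$seg, synth, rev(s$batches$val), gamma = 0, eta_s = 0.1)
  expect_equal(a$S_prime, b$S_prime, tolerance = 1e-15)

  # gamma scales the real-data contribution linearly in the gradient
  g0 <- virtual_seg_step(s$seg, synth, real, gamma = 0, eta_s = 0.1)$grads
  g1 <- virtual_seg_step(s$seg, synth, real, gamma = 1, eta_s = 0.1)$grads
  g2 <- virtual_seg_step(s$seg, synth, real, gamma = 2, eta_s = 0.1)$grads
  for (nm in names(g0)) {
    expect_equal(g2[[nm]] - g0[[nm]], 2 * (g1[[nm]] - g0[[nm]]),
                 tolerance = 1e-10)
  }
})

test_that("exact unrolled architecture gradient matches finite differences", {
  s <- tiny_mlo_setup()
  cfg <- mlo_config(eta_g = 0.2, eta_h = 0.2, eta_s = 0.2, iterations = 1L,
                    warmup = 0L)
  gA <- architecture_gradient(s$gen, s$disc, s$seg, s$arch, s$batches, cfg)

  a0 <- alphas_of(s$arch)
  pipeline_val <- function(logits) {
    pl <- genaug:::mlo_pipeline(s$gen, s$disc, s$seg, logits, s$batches$gan,
                                s$batches$aug_masks, s$batches$train,
                                s$batches$val, cfg, stage2_alphas = a0)
    pl$L_val$value
  }
  h <- 1e-5
  fd <- array(NA_real_, dim = dim(s$arch$logits))
  for (i in seq_along(s$arch$logits)) {
    lp <- s$arch$logits; lm <- s$arch$logits
    lp[i] <- lp[i] + h; lm[i] <- lm[i] - h
    fd[i] <- (pipeline_val(lp) - pipeline_val(lm)) / (2 * h)
  }
  expect_lt(max(abs(gA - fd) / pmax(abs(fd), 1e-8)), 1e-4)
})

test_that("zero learning rates sever the architecture gradient exactly", {
  s <- tiny_mlo_setup()
  g0 <- architecture_gradient(s$gen, s$disc, s$seg, s$arch, s$batches,
                              mlo_config(eta_g = 0, eta_s = 0.2, warmup = 0L))
  expect_identical(max(abs(g0)), 0)
  g1 <- architecture_gradient(s$gen, s$disc, s$seg, s$arch, s$batches,
                              mlo_config(eta_g = 0.2, eta_s = 0, warmup = 0L))
  expect_identical(max(abs(g1)), 0)
  g2 <- architecture_gradient(s$gen, s$disc, s$seg, s$arch, s$batches,
                              mlo_config(eta_g = 0.2, eta_s = 0.2, warmup = 0L))
  expect_gt(max(abs(g2)), 0)
})

test_that("a zero architecture rate freezes the logits over iterations", {
  s <- tiny_mlo_setup()
  state <- list(gen = s$gen, disc = s$disc, seg = s$seg, arch = s$arch)
  cfg <- mlo_config(eta_a = 0, iterations = 1L, warmup = 0L)
  for (i in 1:10) state <- mlo_iteration(state, s$batches, cfg)
  expect_identical(state$arch$logits, s$arch$logits)
  expect_false(identical(state$seg$params, s$seg$params))

  # with a positive rate the logits move
  state2 <- list(gen = s$gen, disc = s$disc, seg = s$seg, arch = s$arch)
  cfg2 <- mlo_config(eta_a = 0.05, iterations = 1L, warmup = 0L)
  state2 <- mlo_iteration(state2, s$batches, cfg2)
  expect_false(identical(state2$arch$logits, s$arch$logits))
})

test_that("iterations are deterministic given the state and batches", {
  s <- tiny_mlo_setup()
  cfg <- mlo_config(iterations = 1L, warmup = 0L)
  st1 <- list(gen = s$gen, disc = s$disc, seg = s$seg, arch = s$arch)
  st2 <- list(gen = s$gen, disc = s$disc, seg = s$seg, arch = s$arch)
  for (i in 1:3) {
    st1 <- mlo_iteration(st1, s$batches, cfg)
    st2 <- mlo_iteration(st2, s$batches, cfg)
  }
  expect_identical(st1$gen$params, st2$gen$params)
  expect_identical(st1$arch$logits, st2$arch$logits)
  expect_identical(st1$last, st2$last)
})

small_splits <- function() {
  list(tr = crop_pairs(tiny_dataset(n = 6, size = 16, seed = 7, noise_sd = 0.1)),
       va = crop_pairs(tiny_dataset(n = 3, size = 16, seed = 8, noise_sd = 0.1,
                                    split = "validation")))
}

small_opts <- list(depth = 1L, gen_base_width = 2L, disc_base_width = 2L,
                   seg_base_width = 2L)

validate_metric_check <- function(fit, va) {
  seg <- best_segmenter(fit)
  preds <- predict_mask(seg, lapply(va$pairs, `[[`, "image"))
  mean(vapply(seq_along(preds),
              function(i) dice_score(preds[[i]], va$pairs[[i]]$mask),
              numeric(1)))
}

test_that("training runs checkpoint at the maximum recorded validation", {
  sp <- small_splits()
  cfg <- mlo_config(iterations = 12L, warmup = 3L, seed = 1L, batch_gan = 3L,
                    batch_seg = 3L)
  for (fit in list(train_genseg(sp$tr, sp$va, cfg, small_opts),
                   train_vanilla(sp$tr, sp$va, cfg, small_opts))) {
    expect_equal(fit$best$metric, max(fit$val_history$metric))
    expect_true(fit$best$iteration %in% fit$val_history$iteration)
    expect_true(all(is.finite(fit$history$l_seg_real) |
                    is.na(fit$history$l_seg_real)))
    got <- validate_metric_check(fit, sp$va)
    expect_equal(got, fit$best$metric, tolerance = 1e-12)
  }
})

test_that("identical seeds give identical checkpoints", {
  sp <- small_splits()
  cfg <- mlo_config(iterations = 6L, warmup = 2L, seed = 5L, batch_gan = 3L,
                    batch_seg = 3L)
  f1 <- train_genseg(sp$tr, sp$va, cfg, small_opts)
  f2 <- train_genseg(sp$tr, sp$va, cfg, small_opts)
  expect_identical(f1$best$seg_params, f2$best$seg_params)
  expect_identical(f1$arch$logits, f2$arch$logits)
  expect_identical(f1$history, f2$history)
})

test_that("the separate baseline never updates the architecture", {
  sp <- small_splits()
  cfg <- mlo_config(iterations = 8L, warmup = 2L, seed = 2L, batch_gan = 3L,
                    batch_seg = 3L)
  fit <- train_separate(sp$tr, sp$va, cfg, small_opts)
  expect_true(all(fit$arch$logits == 0))
  expect_equal(fit$best$metric, max(fit$val_history$metric))
  # same interface as the end-to-end trainer
  full <- train_genseg(sp$tr, sp$va,
                       mlo_config(iterations = 2L, warmup = 1L, seed = 2L,
                                  batch_gan = 3L, batch_seg = 3L), small_opts)
  expect_identical(sort(names(fit)), sort(names(full)))
  expect_s3_class(best_segmenter(fit), "segmenter")
})

test_that("training rejects empty splits and iterations = 1 works", {
  sp <- small_splits()
  empty <- seg_dataset(list())
  expect_error(train_genseg(empty, sp$va), "non-empty")
  expect_error(train_vanilla(sp$tr, empty), "non-empty")
  fit <- train_vanilla(sp$tr, sp$va,
                       mlo_config(iterations = 1L, seed = 1L), small_opts)
  expect_identical(nrow(fit$history), 1L)
  expect_identical(fit$best$iteration, 1L)
})

test_that("tidy and glance expose the training record", {
  sp <- small_splits()
  fit <- train_vanilla(sp$tr, sp$va,
                       mlo_config(iterations = 4L, seed = 3L), small_opts)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 4L)
  gl <- glance(fit)
  expect_identical(gl$method, "vanilla")
  expect_equal(gl$best_val, fit$best$metric)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
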