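ad <- function(name) get(name, envir = asNamespace("genaug"))

test_that("selection-weight normalization is a per-cell softmax", {
  expect_equal(normalize_alphas(c(0, 0, 0)), rep(1 / 3, 3))
  a <- normalize_alphas(c(10, 0, 0))
  expect_gt(a[1], 0.999)
  lg <- with_seed_(1, matrix(rnorm(12), 3, 4))
  al <- normalize_alphas(lg)
  expect_equal(colSums(al), rep(1, 4), tolerance = 1e-12)
  expect_true(all(al > 0 & al < 1))
  expect_error(normalize_alphas(c(1, Inf, 0)), "non-finite")
})

test_that("every candidate in the pool maps to the same output shape", {
  # analytic: kernel - 2*padding == stride == 2 for 421/622/823
  for (cand in default_candidate_pool()) {
    expect_identical(cand$kernel - 2L * cand$padding, cand$stride)
    expect_identical(ad("conv_out_size")(12L, cand$kernel, cand$stride,
                                         cand$padding), 6L)
  }
  expect_error(genaug:::check_pool(list(list(kernel = 5L, stride = 2L,
                                             padding = 1L))),
               "shape-compatible")
})

test_that("one-hot selection collapses the cell to a single operator", {
  ga <- build_searchable_generator(16L, depth = 1L, base_width = 2L, seed = 5)
  gen <- ga$generator
  m <- tiny_dataset(n = 1, size = 16, seed = 4)$pairs[[1]]$mask
  for (k in 1:3) {
    lg <- matrix(-50, 3, 2); lg[k, ] <- 50
    img_mix <- generate_image(gen, arch_weights(lg), m)
    hard <- discretize_architecture(arch_weights(lg))
    expect_identical(hard$onehot, c(k, k))
    img_hard <- generate_image(gen, hard, m)
    expect_equal(img_mix, img_hard, tolerance = 1e-12)
  }
})

test_that("cell output is linear in the selection weights", {
  ga <- build_searchable_generator(8L, depth = 1L, base_width = 1L, seed = 2)
  gen <- ga$generator
  x <- ad("ad_const")(with_seed_(3, matrix(rnorm(2 * 64), 2)))
  mix <- function(avec) {
    an <- ad("ad_const")(matrix(avec, 3, 1))
    pn <- ad("leaf_params")(gen$params, requires_grad = FALSE)
    ad("cell_mix_forward")(x, pn, "enc1", an, 1L, gen$config$pool,
                           8L, 8L, 2L, 1L, transposed = FALSE)$y$value
  }
  a1 <- c(0.5, 0.3, 0.2); a2 <- c(0.1, 0.1, 0.8)
  lam <- 0.37
  expect_equal(mix(lam * a1 + (1 - lam) * a2),
               lam * mix(a1) + (1 - lam) * mix(a2), tolerance = 1e-12)

  # convex mixture equals the alpha-weighted sum of direct-conv oracles
  xarr <- array(0, dim = c(2, 8, 8))
  for (ci in 1:2) xarr[ci, , ] <- matrix(x$value[ci, ], 8, 8)
  want <- 0
  for (k in 1:3) {
    cand <- gen$config$pool[[k]]
    w <- gen$params[[paste0("enc1.b", k, ".w")]]
    b <- gen$params[[paste0("enc1.b", k, ".bias")]]
    want <- want + a1[k] * conv_oracle(xarr, w, b, cand$stride, cand$padding)
  }
  got <- mix(a1)
  flat <- array(0, dim = dim(want))
  for (o in seq_len(dim(want)[1])) flat[o, , ] <- matrix(got[o, ], 4, 4)
  expect_lt(max(abs(flat - want)), 1e-10)
})

test_that("the generator honours its forward contract", {
  ga <- build_searchable_generator(16L, depth = 2L, base_width = 3L, seed = 9)
  gen <- ga$generator; arch <- ga$arch
  m <- tiny_dataset(n = 1, size = 16, seed = 10)$pairs[[1]]$mask

  i1 <- generate_image(gen, arch, m)
  i2 <- generate_image(gen, arch, m)
  expect_identical(i1, i2)
  expect_identical(dim(i1), dim(m))
  expect_true(all(i1 >= -1 & i1 <= 1))

  empty <- generate_image(gen, arch, matrix(0L, 16, 16))
  expect_true(all(is.finite(empty)))

  bad <- m; bad[1, 1] <- 7L
  expect_error(generate_image(gen, arch, bad), "label")
  expect_error(generate_image(gen, arch, matrix(0L, 8, 8)), "size")
  expect_error(build_searchable_generator(16L, depth = 0L), "at least 1")
  expect_error(build_searchable_generator(20L, depth = 3L), "divisible")
})

test_that("stride arithmetic gives the expected bottleneck", {
  ga <- build_searchable_generator(64L, depth = 4L, base_width = 2L, seed = 1)
  plan <- ga$generator$config$plan
  expect_identical(length(plan$cw), 5L)
  size <- 64L
  for (d in 1:4) size <- ad("conv_out_size")(size, 4L, 2L, 1L)
  expect_identical(size, 4L)
})

test_that("discretization retains the argmax with low-index tie-break", {
  a <- arch_weights(matrix(log(c(0.7, 0.2, 0.1)), 3, 1))
  expect_identical(discretize_architecture(a)$onehot, 1L)
  b <- arch_weights(matrix(c(1, 1, -5), 3, 1))
  expect_identical(discretize_architecture(b)$onehot, 1L)  # tie -> lowest
  u <- arch_weights(matrix(0, 3, 1))
  expect_identical(discretize_architecture(u)$onehot, 1L)
  d <- discretize_architecture(arch_weights(matrix(c(0, 3, 1, 9, 2, 1), 3, 2)))
  expect_equal(alphas_of(d), matrix(c(0, 1, 0, 1, 0, 0), 3, 2))
})

test_that("adversarial losses have their closed forms", {
  half <- gan_loss_terms(p_real = rep(0.5, 4), p_fake = rep(0.5, 4))
  expect_equal(half$bce_real, log(2), tolerance = 1e-12)
  expect_equal(half$bce_fake, log(2), tolerance = 1e-12)
  expect_equal(half$l_g, log(2), tolerance = 1e-12)

  hand <- gan_loss_terms(0.8, 0.3)
  expect_equal(hand$l_d, -(log(0.8) + log(0.7)) / 2, tolerance = 1e-12)
  expect_equal(hand$l_g, -log(0.3), tolerance = 1e-12)

  sharp <- gan_loss_terms(rep(1 - 1e-12, 3), rep(1e-12, 3))
  expect_lt(sharp$l_d, 1e-10)
})

test_that("model-level adversarial losses are finite and need batches", {
  ds <- tiny_dataset(n = 4, size = 16, seed = 6)
  ga <- build_searchable_generator(16L, depth = 1L, base_width = 2L, seed = 2)
  disc <- build_discriminator(16L, base_width = 2L, seed = 3)
  fake_imgs <- generate_image(ga$generator, ga$arch,
                              lapply(ds$pairs[3:4], `[[`, "mask"))
  fakes <- lapply(1:2, function(i) {
    list(image = fake_imgs[[i]], mask = ds$pairs[[2 + i]]$mask)
  })
  l <- gan_losses(disc, ds$pairs[1:2], fakes)
  expect_true(is.finite(l$l_d) && is.finite(l$l_g))
  expect_gt(l$l_d, 0)
  expect_error(gan_losses(disc, list(), fakes), "non-empty")
})
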