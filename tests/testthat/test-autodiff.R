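# The engine under the whole package: reverse-mode gradients that can be
# differentiated again.  Checked against finite differences and direct-loop
# convolution oracles.

ad <- function(name) get(name, envir = asNamespace("genaug"))

test_that("composite gradients match central finite differences", {
  ad_leaf <- ad("ad_leaf"); ad_grad <- ad("ad_grad")
  f <- function(x) {
    xl <- ad_leaf(x, TRUE)
    y <- ad("ad_tanh")(ad("ad_matmul")(ad("ad_const")(matrix(1:6 / 7, 2, 3)),
                                       ad("ad_reshape")(xl, c(3, 2))))
    list(z = ad("ad_mean")(ad("ad_mul")(y, y)), xl = xl)
  }
  x0 <- with_seed_(1, rnorm(6))
  r <- f(x0)
  g <- ad_grad(r$z, r$xl)$value
  h <- 1e-6
  fd <- sapply(seq_along(x0), function(i) {
    xp <- x0; xm <- x0
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp)$z$value - f(xm)$z$value) / (2 * h)
  })
  expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-10)), 1e-6)
})

test_that("double backward (Hessian-vector products) is exact", {
  ad_leaf <- ad("ad_leaf"); ad_grad <- ad("ad_grad")
  f <- function(x) {
    xl <- ad_leaf(x, TRUE)
    y <- ad("ad_sigmoid")(ad("ad_matmul")(ad("ad_const")(matrix(1:6 / 5, 2, 3)),
                                          ad("ad_reshape")(xl, c(3, 2))))
    list(z = ad("ad_mean")(ad("ad_mul")(y, y)), xl = xl)
  }
  x0 <- with_seed_(2, rnorm(6))
  v <- with_seed_(3, rnorm(6))
  r <- f(x0)
  gn <- ad_grad(r$z, r$xl)
  s <- ad("ad_sum")(ad("ad_mul")(gn, ad("ad_const")(v)))
  hvp <- ad_grad(s, r$xl)$value
  h <- 1e-5
  fd <- sapply(seq_along(x0), function(i) {
    xp <- x0; xm <- x0
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    ra <- f(xp); rb <- f(xm)
    sum((ad_grad(ra$z, ra$xl)$value - ad_grad(rb$z, rb$xl)$value) * v) / (2 * h)
  })
  expect_lt(max(abs(hvp - fd)), 1e-7)
})

test_that("strided convolution matches a direct-loop oracle", {
  H <- 5L; W <- 6L; Cin <- 2L; Cout <- 3L; k <- 4L
  x <- with_seed_(4, array(rnorm(Cin * H * W), dim = c(Cin, H, W)))
  w <- with_seed_(5, array(rnorm(Cout * Cin * k * k), dim = c(Cout, Cin, k, k)))
  b <- with_seed_(6, rnorm(Cout))
  # package path: column-major (C x B*H*W) layout, batch of one
  xmat <- matrix(0, Cin, H * W)
  for (ci in seq_len(Cin)) xmat[ci, ] <- as.vector(x[ci, , ])
  res <- ad("nn_conv2d")(ad("ad_const")(xmat), ad("ad_const")(w),
                         ad("ad_const")(b), H, W, Cin, 1L, k, 2L, 1L)
  want <- conv_oracle(x, w, b, stride = 2, pad = 1)
  got <- array(0, dim = dim(want))
  for (o in seq_len(Cout)) got[o, , ] <- matrix(res$y$value[o, ], res$H, res$W)
  expect_lt(max(abs(got - want)), 1e-12)
})

test_that("transposed convolution is the exact adjoint of convolution", {
  # <conv(x; w), y> must equal <x, upconv(y; w)> with the shared weight
  # array read as (Cout, Cin, k, k) by the convolution and (Cin, Cout, k, k)
  # by its transpose
  Hs <- 4L; Cs <- 2L; Co <- 3L; k <- 6L; s <- 2L; p <- 2L
  Hb <- Hs * s
  y_small <- with_seed_(7, matrix(rnorm(Co * Hs * Hs), Co))
  x_big <- with_seed_(8, matrix(rnorm(Cs * Hb * Hb), Cs))
  w <- with_seed_(9, array(rnorm(Co * Cs * k * k), dim = c(Co, Cs, k, k)))
  cv <- ad("nn_conv2d")(ad("ad_const")(x_big), ad("ad_const")(w),
                        ad("ad_const")(numeric(Co)), Hb, Hb, Cs, 1L, k, s, p)
  up <- ad("nn_upconv2d")(ad("ad_const")(y_small), ad("ad_const")(w),
                          ad("ad_const")(numeric(Cs)), Hs, Hs, Co, 1L, k, s, p)
  expect_identical(c(cv$H, cv$W), c(Hs, Hs))
  expect_identical(c(up$H, up$W), c(Hb, Hb))
  expect_equal(sum(cv$y$value * y_small), sum(x_big * up$y$value),
               tolerance = 1e-12)
})

test_that("network gradients through norm and cross-entropy match FD", {
  H <- 6L; W <- 6L; Cin <- 1L; Cout <- 3L; k <- 4L; B <- 2L
  x <- with_seed_(10, matrix(rnorm(Cin * B * H * W), Cin))
  b <- with_seed_(11, rnorm(Cout))
  labs <- with_seed_(12, sample(0:(Cout - 1), B * 9, replace = TRUE))
  net <- function(wv) {
    wl <- ad("ad_leaf")(array(wv, dim = c(Cout, Cin, k, k)), TRUE)
    cv <- ad("nn_conv2d")(ad("ad_const")(x), wl, ad("ad_const")(b),
                          H, W, Cin, B, k, 2L, 1L)
    yn <- ad("nn_instance_norm")(cv$y, Cout, B, cv$H * cv$W)
    list(loss = ad("nn_softmax_ce")(yn, labs), wl = wl)
  }
  w0 <- with_seed_(13, rnorm(Cout * Cin * k * k))
  r <- net(w0)
  g <- as.vector(ad("ad_grad")(r$loss, r$wl)$value)
  idx <- with_seed_(14, sample(length(w0), 8))
  h <- 1e-6
  fd <- sapply(idx, function(i) {
    wp <- w0; wm <- w0
    wp[i] <- wp[i] + h; wm[i] <- wm[i] - h
    (net(wp)$loss$value - net(wm)$loss$value) / (2 * h)
  })
  expect_lt(max(abs(g[idx] - fd) / pmax(abs(fd), 1e-8)), 1e-5)
})
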