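# Convolutional building blocks expressed through the autodiff ops.
#
# Feature maps are stored as (channels x batch*H*W) matrices with the
# spatial index column-major (row fastest), batches outermost, matching
# as.vector() on an H x W matrix.  Convolutions are im2col gathers followed
# by a matrix product; transposed convolutions are the exact adjoint
# (scatter of the weight-transposed product), so both are linear maps whose
# derivatives stay inside the op set.

.nn_cache <- new.env(parent = emptyenv())

conv_out_size <- function(H, k, stride, pad) (H + 2L * pad - k) %/% stride + 1L

# Linear indices mapping an input (C x B*H*W) to its im2col matrix
# (C*k*k x B*Ho*Wo).  Out-of-range taps point at a trailing zero slot.
im2col_index <- function(H, W, C, B, k, stride, pad) {
  key <- paste("i2c", H, W, C, B, k, stride, pad, sep = "_")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)

  Ho <- conv_out_size(H, k, stride, pad)
  Wo <- conv_out_size(W, k, stride, pad)
  stopifnot(Ho >= 1L, Wo >= 1L)
  R <- C * k * k
  N <- B * Ho * Wo

  r <- seq_len(R) - 1L
  cc <- r %% C + 1L
  ki <- (r %/% C) %% k + 1L
  kj <- r %/% (C * k) + 1L

  n <- seq_len(N) - 1L
  b <- n %/% (Ho * Wo) + 1L
  s <- n %% (Ho * Wo)
  wo <- s %/% Ho + 1L
  ho <- s %% Ho + 1L

  HI <- outer(ki, (ho - 1L) * stride, "+") - pad       # R x N input rows
  WI <- outer(kj, (wo - 1L) * stride, "+") - pad
  Bm <- matrix(rep(b, each = R), R, N)
  Cm <- matrix(cc, R, N)

  lin <- Cm + C * ((Bm - 1L) * (H * W) + (WI - 1L) * H + HI - 1L)
  bad <- HI < 1L | HI > H | WI < 1L | WI > W
  lin[bad] <- C * B * H * W + 1L

  ok <- which(!bad)
  G <- Matrix::sparseMatrix(i = ok, j = as.integer(lin)[ok], x = 1,
                            dims = c(R * N, C * B * H * W))
  out <- list(idx = as.integer(lin), R = R, N = N, Ho = Ho, Wo = Wo,
              G = G, Gt = Matrix::t(G))
  .nn_cache[[key]] <- out
  out
}

# x: (Cin x B*H*W) node; w: (Cout, Cin, k, k) array node; b: length-Cout node
nn_conv2d <- function(x, w, b, H, W, Cin, B, k, stride, pad) {
  map <- im2col_index(H, W, Cin, B, k, stride, pad)
  Cout <- dim(w$value)[1L]
  cols <- ad_spmap(x, map$G, map$Gt, c(map$R, map$N))
  wmat <- ad_reshape(w, c(Cout, Cin * k * k))
  y <- ad_affine(wmat, cols, b)
  list(y = y, H = map$Ho, W = map$Wo, C = Cout)
}

# Transposed convolution from (Cin x B*H*W) to (Cout x B*sH*sW) for the
# shipped pool (k - 2*pad == stride).  w: (Cin, Cout, k, k) array node.
nn_upconv2d <- function(x, w, b, H, W, Cin, B, k, stride, pad) {
  Hb <- (H - 1L) * stride + k - 2L * pad
  Wb <- (W - 1L) * stride + k - 2L * pad
  Cout <- dim(w$value)[2L]
  map <- im2col_index(Hb, Wb, Cout, B, k, stride, pad)
  stopifnot(map$Ho == H, map$Wo == W)
  wmat <- ad_reshape(w, c(Cin, Cout * k * k))
  cols <- ad_cross(wmat, x)
  y <- ad_spmap(cols, map$Gt, map$G, c(Cout, B * Hb * Wb))
  y <- ad_addbias(y, b)
  list(y = y, H = Hb, W = Wb, C = Cout)
}

in_norm_mats <- function(B, HW) {
  key <- paste("in", B, HW, sep = "_")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  Mavg <- matrix(0, B * HW, B)
  Mexp <- matrix(0, B, B * HW)
  for (b in seq_len(B)) {
    rows <- (b - 1L) * HW + seq_len(HW)
    Mavg[rows, b] <- 1 / HW
    Mexp[b, rows] <- 1
  }
  out <- list(avg = Mavg, exp = Mexp, avg_t = t(Mavg), exp_t = t(Mexp))
  .nn_cache[[key]] <- out
  out
}

# Instance normalization (no affine terms): per channel and per sample,
# subtract the spatial mean and divide by the spatial standard deviation.
nn_instance_norm <- function(x, C, B, HW, eps = 1e-5) {
  m <- in_norm_mats(B, HW)
  mu <- ad_cmmr(x, m$avg, m$avg_t)
  xc <- ad_sub(x, ad_cmmr(mu, m$exp, m$exp_t))
  v <- ad_cmmr(ad_mul(xc, xc), m$avg, m$avg_t)
  sd <- ad_sqrt(ad_add(v, ad_const(matrix(eps, C, B))))
  ad_div(xc, ad_cmmr(sd, m$exp, m$exp_t))
}

# Mean pixel-wise cross-entropy of scores (L x N) against 0-based labels,
# computed with the usual max-shift for stability; the shift is a constant
# and does not perturb the gradient.
nn_softmax_ce <- function(scores, labels) {
  L <- nrow(scores$value)
  N <- ncol(scores$value)
  stopifnot(length(labels) == N)
  m <- apply(scores$value, 2L, max)
  Zc <- ad_sub(scores, ad_const(matrix(m, L, N, byrow = TRUE)))
  s <- ad_colsums(ad_exp(Zc))
  idx <- as.integer(labels) + 1L + L * (seq_len(N) - 1L)
  picked <- ad_sum(ad_gather(scores, idx, N))
  total <- ad_sub(ad_add(ad_sum(ad_log(s)), ad_const(sum(m))), picked)
  ad_smul(total, 1 / N)
}

## ---- plain-numeric helpers (no graph) -------------------------------------

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# one-hot encode a list of H x W integer masks into (L x B*H*W)
onehot_masks <- function(masks, L) {
  labs <- unlist(lapply(masks, as.vector), use.names = FALSE)
  if (any(labs < 0 | labs >= L)) {
    stop("mask contains labels outside the configured set {0..", L - 1L, "}")
  }
  n <- length(labs)
  out <- matrix(0, L, n)
  out[as.integer(labs) + 1L + L * (seq_len(n) - 1L)] <- 1
  out
}

# stack a list of H x W (or H x W x C) images into (C x B*H*W)
stack_images <- function(images) {
  mats <- lapply(images, function(img) {
    d <- dim(img)
    if (length(d) == 2L) {
      matrix(as.vector(img), nrow = 1L)
    } else {
      t(matrix(as.vector(img), d[1L] * d[2L], d[3L]))
    }
  })
  do.call(cbind, mats)
}

# split a (C x B*H*W) matrix back into B images (H x W or H x W x C)
unstack_images <- function(x, H, W, B) {
  C <- nrow(x)
  lapply(seq_len(B), function(b) {
    cols <- (b - 1L) * H * W + seq_len(H * W)
    block <- x[, cols, drop = FALSE]
    if (C == 1L) matrix(block[1L, ], H, W) else array(t(block), dim = c(H, W, C))
  })
}

# glorot/he-style initialization helpers (caller controls the RNG state)
init_array <- function(dm, fan_in) {
  array(stats::rnorm(prod(dm), sd = sqrt(2 / fan_in)), dim = dm)
}

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a stream of sub-seeds from a master seed, kept inside 32-bit range
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483647) + 1L
}
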