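# Reverse-mode automatic differentiation with double-backward support.
#
# The trilevel solver needs exact gradients of a validation loss taken
# *through* one-step gradient updates (cross second derivatives of the GAN
# and segmentation losses).  To make that exact rather than approximated,
# every backward pass here is itself built out of graph nodes, so gradients
# can be differentiated again ("create_graph" semantics).  The op set is
# deliberately small: what the conditional generator, discriminator and
# U-Net forwards need, expressed so that every vector-Jacobian product is a
# composition of the same ops.
#
# A node is an environment holding `value` (numeric array), `parents`,
# `vjps` (one function per parent mapping the incoming gradient node to a
# contribution node, or NULL for non-differentiable arguments), a
# `req`(uires-gradient) flag and a creation `id`.  Nodes are only ever
# created from already-existing parents, so creation order is a valid
# topological order and the backward sweep is a single pass in decreasing id.

.ad <- new.env(parent = emptyenv())
.ad$id <- 0L

ad_dim <- function(x) {
  d <- dim(x)
  if (is.null(d)) length(x) else d
}

new_node <- function(value, parents = list(), vjps = list(), req = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$vjps <- vjps
  if (is.null(req)) {
    req <- FALSE
    for (p in parents) if (isTRUE(p$req)) { req <- TRUE; break }
  }
  e$req <- req
  .ad$id <- .ad$id + 1L
  e$id <- .ad$id
  e$k <- as.character(e$id)
  class(e) <- "adnode"
  e
}

#' @export
print.adnode <- function(x, ...) {
  cat("<adnode id=", x$id, " dim=", paste(ad_dim(x$value), collapse = "x"),
      " req=", x$req, ">\n", sep = "")
  invisible(x)
}

ad_leaf <- function(value, requires_grad = FALSE) {
  new_node(value, req = requires_grad)
}

ad_const <- function(value) new_node(value, req = FALSE)

is_adnode <- function(x) inherits(x, "adnode")

# promote plain numerics so ops can take constants directly
as_node <- function(x) if (is_adnode(x)) x else ad_const(x)

ad_zeros_like <- function(x) {
  d <- ad_dim(x$value)
  v <- if (length(d) > 1L) array(0, dim = d) else numeric(d)
  ad_const(v)
}

## ---- arithmetic -----------------------------------------------------------

ad_add <- function(a, b) {
  new_node(a$value + b$value, list(a, b),
           list(function(g) g, function(g) g))
}

ad_sub <- function(a, b) {
  new_node(a$value - b$value, list(a, b),
           list(function(g) g, function(g) ad_neg(g)))
}

ad_neg <- function(a) {
  new_node(-a$value, list(a), list(function(g) ad_neg(g)))
}

# multiply by a plain scalar constant; a zero factor severs the graph, which
# is both exact and what makes the zero-learning-rate degeneracies literal
ad_smul <- function(a, k) {
  if (k == 0) return(ad_zeros_like(a))
  new_node(k * a$value, list(a), list(function(g) ad_smul(g, k)))
}

# node-scalar times node-tensor
ad_scalar_mul <- function(s, x) {
  new_node(as.numeric(s$value) * x$value, list(s, x),
           list(function(g) ad_sum(ad_mul(g, x)),
                function(g) ad_scalar_mul(s, g)))
}

ad_mul <- function(a, b) {
  stopifnot(length(a$value) == length(b$value))
  new_node(a$value * b$value, list(a, b),
           list(function(g) ad_mul(g, b),
                function(g) ad_mul(g, a)))
}

ad_div <- function(a, b) {
  stopifnot(length(a$value) == length(b$value))
  new_node(a$value / b$value, list(a, b),
           list(function(g) ad_div(g, b),
                function(g) ad_neg(ad_div(ad_mul(g, a), ad_mul(b, b)))))
}

## ---- linear algebra -------------------------------------------------------

ad_t <- function(a) {
  new_node(t(a$value), list(a), list(function(g) ad_t(g)))
}

# a %*% b, t(a) %*% b and a %*% t(b); the three are closed under
# differentiation, avoiding explicit transpose copies in backward passes
ad_matmul <- function(a, b) {
  new_node(a$value %*% b$value, list(a, b),
           list(function(g) ad_tcross(g, b),
                function(g) ad_cross(a, g)))
}

ad_cross <- function(a, b) {
  new_node(crossprod(a$value, b$value), list(a, b),
           list(function(g) ad_tcross(b, g),
                function(g) ad_matmul(a, g)))
}

ad_tcross <- function(a, b) {
  new_node(tcrossprod(a$value, b$value), list(a, b),
           list(function(g) ad_matmul(g, b),
                function(g) ad_cross(g, a)))
}

# constant-matrix products (linear maps with fixed coefficients);
# pass the precomputed transpose when the map is reused across iterations
ad_cmml <- function(M, x, Mt = t(M)) {
  new_node(M %*% x$value, list(x), list(function(g) ad_cmml(Mt, g, M)))
}

ad_cmmr <- function(x, M, Mt = t(M)) {
  new_node(x$value %*% M, list(x), list(function(g) ad_cmmr(g, Mt, M)))
}

# sparse-map gather/scatter: y = S %*% vec(x) for a cached sparse selection
# matrix (one 1 per retained tap); the adjoint uses the cached transpose
ad_spmap <- function(x, S, St, outdim) {
  v <- as.numeric(S %*% as.vector(x$value))
  dim(v) <- if (length(outdim) > 1L) outdim else NULL
  indim <- ad_dim(x$value)
  new_node(v, list(x), list(function(g) ad_spmap(g, St, S, indim)))
}

## ---- reductions / broadcasts ---------------------------------------------

ad_sum <- function(a) {
  dm <- ad_dim(a$value)
  new_node(sum(a$value), list(a), list(function(g) ad_fill(g, dm)))
}

ad_fill <- function(s, dm) {
  v <- if (length(dm) > 1L) array(as.numeric(s$value), dim = dm) else {
    rep(as.numeric(s$value), dm)
  }
  new_node(v, list(s), list(function(g) ad_sum(g)))
}

ad_mean <- function(a) ad_smul(ad_sum(a), 1 / length(a$value))

ad_rowsums <- function(a) {
  nc <- ncol(a$value)
  new_node(rowSums(a$value), list(a),
           list(function(g) ad_colbcast(g, nc)))
}

ad_colbcast <- function(v, nc) {
  nr <- length(v$value)
  new_node(matrix(v$value, nr, nc), list(v),
           list(function(g) ad_rowsums(g)))
}

ad_colsums <- function(a) {
  nr <- nrow(a$value)
  new_node(colSums(a$value), list(a),
           list(function(g) ad_rowbcast(g, nr)))
}

ad_rowbcast <- function(v, nr) {
  nc <- length(v$value)
  new_node(matrix(v$value, nr, nc, byrow = TRUE), list(v),
           list(function(g) ad_colsums(g)))
}

# matrix (r x c) plus per-row bias vector (length r)
ad_addbias <- function(x, b) {
  new_node(x$value + b$value, list(x, b),
           list(function(g) g, function(g) ad_rowsums(g)))
}

# fused affine map w %*% x + b (b recycled per row); the workhorse of every
# convolution after im2col, fused to keep the graph small
ad_affine <- function(w, x, b) {
  new_node(w$value %*% x$value + b$value, list(w, x, b),
           list(function(g) ad_tcross(g, x),
                function(g) ad_cross(w, g),
                function(g) ad_rowsums(g)))
}

## ---- indexing -------------------------------------------------------------

# y = c(as.vector(x), 0)[idx]; idx may address the trailing zero (length+1)
# for zero-padding. Its adjoint is scatter-add, and vice versa, so both are
# closed under differentiation.
ad_gather <- function(x, idx, outdim) {
  n <- length(x$value)
  v <- c(as.vector(x$value), 0)[idx]
  dim(v) <- if (length(outdim) > 1L) outdim else NULL
  indim <- ad_dim(x$value)
  new_node(v, list(x),
           list(function(g) ad_scatter(g, idx, n, indim)))
}

ad_scatter <- function(x, idx, n, outdim) {
  acc <- numeric(n + 1L)
  rs <- rowsum(as.vector(x$value), idx, reorder = FALSE)
  acc[as.integer(rownames(rs))] <- rs[, 1L]
  v <- acc[seq_len(n)]
  dim(v) <- if (length(outdim) > 1L) outdim else NULL
  indim <- ad_dim(x$value)
  new_node(v, list(x),
           list(function(g) ad_gather(g, idx, indim)))
}

ad_reshape <- function(x, dm) {
  v <- x$value
  dim(v) <- if (length(dm) > 1L) dm else NULL
  indim <- ad_dim(x$value)
  new_node(v, list(x), list(function(g) ad_reshape(g, indim)))
}

ad_rbind <- function(a, b) {
  ra <- nrow(a$value)
  rb <- nrow(b$value)
  new_node(rbind(a$value, b$value), list(a, b),
           list(function(g) ad_rows(g, seq_len(ra)),
                function(g) ad_rows(g, ra + seq_len(rb))))
}

ad_rows <- function(x, rows) {
  nr <- nrow(x$value)
  new_node(x$value[rows, , drop = FALSE], list(x),
           list(function(g) ad_rowpad(g, rows, nr)))
}

ad_rowpad <- function(x, rows, nr_total) {
  v <- matrix(0, nr_total, ncol(x$value))
  v[rows, ] <- x$value
  new_node(v, list(x), list(function(g) ad_rows(g, rows)))
}

## ---- elementwise nonlinearities ------------------------------------------

ad_tanh <- function(a) {
  y <- new_node(tanh(a$value), list(a), list(NULL))
  y$vjps <- list(function(g) {
    ones <- ad_const(array(1, dim = ad_dim(y$value)))
    ad_mul(g, ad_sub(ones, ad_mul(y, y)))
  })
  y
}

ad_sigmoid <- function(a) {
  y <- new_node(stats::plogis(a$value), list(a), list(NULL))
  y$vjps <- list(function(g) {
    ones <- ad_const(array(1, dim = ad_dim(y$value)))
    ad_mul(g, ad_mul(y, ad_sub(ones, y)))
  })
  y
}

ad_exp <- function(a) {
  y <- new_node(exp(a$value), list(a), list(NULL))
  y$vjps <- list(function(g) ad_mul(g, y))
  y
}

ad_log <- function(a) {
  new_node(log(a$value), list(a), list(function(g) ad_div(g, a)))
}

ad_sqrt <- function(a) {
  y <- new_node(sqrt(a$value), list(a), list(NULL))
  y$vjps <- list(function(g) ad_div(ad_smul(g, 0.5), y))
  y
}

# softplus computed stably; derivative is the logistic function
ad_softplus <- function(a) {
  v <- a$value
  new_node(log1p(exp(-abs(v))) + pmax(v, 0), list(a),
           list(function(g) ad_mul(g, ad_sigmoid(a))))
}

ad_abs <- function(a) {
  s <- sign(a$value)
  new_node(abs(a$value), list(a),
           list(function(g) ad_mul(g, ad_const(s))))
}

# piecewise-linear units: the active-set mask is locally constant, so using
# it as a constant factor gives the exact derivative almost everywhere
ad_relu <- function(a) {
  m <- (a$value > 0) * 1
  new_node(a$value * m, list(a),
           list(function(g) ad_mul(g, ad_const(m))))
}

ad_lrelu <- function(a, slope = 0.2) {
  m <- ifelse(a$value > 0, 1, slope)
  new_node(a$value * m, list(a),
           list(function(g) ad_mul(g, ad_const(m))))
}

## ---- backward -------------------------------------------------------------

# Gradient of a scalar node w.r.t. a list of nodes.  The returned gradients
# are nodes built from the ops above, so they can be differentiated again.
ad_grad <- function(out, wrt) {
  single <- is_adnode(wrt)
  if (single) wrt <- list(wrt)
  if (!isTRUE(out$req)) {
    res <- lapply(wrt, ad_zeros_like)
    return(if (single) res[[1L]] else res)
  }

  # collect ancestors reachable through requires-grad edges
  nodes <- new.env(parent = emptyenv())
  stack <- list(out)
  ids <- integer(0)
  while (length(stack) > 0L) {
    ndx <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- ndx$k
    if (!is.null(nodes[[key]])) next
    nodes[[key]] <- ndx
    ids <- c(ids, ndx$id)
    for (p in ndx$parents) {
      if (p$req) stack[[length(stack) + 1L]] <- p
    }
  }

  grads <- new.env(parent = emptyenv())
  seed_dim <- ad_dim(out$value)
  seed <- if (length(seed_dim) > 1L) array(1, dim = seed_dim) else rep(1, seed_dim)
  grads[[out$k]] <- ad_const(seed)

  for (key in as.character(sort(ids, decreasing = TRUE))) {
    g <- grads[[key]]
    if (is.null(g)) next
    ndx <- nodes[[key]]
    ps <- ndx$parents
    vj <- ndx$vjps
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!p$req || is.null(vj[[j]])) next
      contrib <- vj[[j]](g)
      pk <- p$k
      cur <- grads[[pk]]
      grads[[pk]] <- if (is.null(cur)) contrib else ad_add(cur, contrib)
    }
  }

  res <- lapply(wrt, function(w) {
    g <- grads[[w$k]]
    if (is.null(g)) ad_zeros_like(w) else g
  })
  if (single) res[[1L]] else res
}

ad_value <- function(x) x$value

## ---- helpers over parameter lists ----------------------------------------

leaf_params <- function(params, requires_grad = TRUE) {
  lapply(params, ad_leaf, requires_grad = requires_grad)
}

values_of <- function(nodes) lapply(nodes, ad_value)

# params' = params - eta * grads, as graph nodes (the virtual step)
step_params <- function(param_nodes, grad_nodes, eta) {
  stopifnot(length(param_nodes) == length(grad_nodes))
  out <- vector("list", length(param_nodes))
  names(out) <- names(param_nodes)
  for (i in seq_along(param_nodes)) {
    out[[i]] <- ad_sub(param_nodes[[i]], ad_smul(grad_nodes[[i]], eta))
  }
  out
}
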