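# Minimal reverse-mode automatic differentiation on matrices.
#
# All neural components in this package (ViT streams, temporal transformer,
# seed encoder, regression head, CNN/LSTM baselines) are expressed as tape
# programs over these ops. A tape is rebuilt per forward pass; heavy work is
# BLAS matmuls, so pure R overhead stays small. Rows of a token matrix that
# belong to different images/sequences are kept contiguous and group-aware ops
# (attention, pooling, tiled adds) take an explicit group count, so a whole
# batch runs through one graph.

#' Create a fresh autodiff tape
#'
#' @param training logical; when `TRUE`, dropout ops are active (inverted
#'   dropout), otherwise they are identities.
#' @return an environment holding the recorded nodes.
#' @keywords internal
ad_tape <- function(training = FALSE) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp$training <- isTRUE(training)
  tp
}

# Record a node. `backward` is NULL for leaves, else function(g) that pushes
# gradients into parent nodes via ad_accum().
#
# `value` must be forced before the id is assigned: it may itself create
# nodes on the tape (ops are routinely nested), and ids must reflect the
# true creation order for the reverse sweep.
ad_node <- function(tape, value, backward = NULL) {
  force(value)
  force(backward)
  id <- tape$n + 1L
  if (id > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$id <- id
  nd$backward <- backward
  tape$nodes[[id]] <- nd
  tape$n <- id
  nd
}

#' Leaf node (parameter or constant input)
#' @keywords internal
ad_leaf <- function(tape, value) ad_node(tape, value)

ad_accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

#' Run the backward sweep from a scalar loss node
#' @keywords internal
ad_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- 1
  for (i in seq.int(loss$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$backward) && !is.null(nd$grad)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

# Wrap a named list of parameter matrices as leaves; returns list of nodes.
ad_leaves <- function(tape, params) lapply(params, function(p) ad_leaf(tape, p))

# Collect gradients (zero where a parameter was unused).
ad_grads <- function(param_nodes) {
  lapply(param_nodes, function(nd) {
    if (is.null(nd$grad)) array(0, dim = dim(nd$value)) else nd$grad
  })
}

## ---- elementwise / linear ops ----

ad_matmul <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, function(g) {
    ad_accum(a, tcrossprod(g, b$value))
    ad_accum(b, crossprod(a$value, g))
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, function(g) {
    ad_accum(a, g)
    ad_accum(b, g)
  })
}

# x + row-vector bias (bias stored as 1 x D matrix)
ad_addvec <- function(tape, a, b) {
  bv <- as.numeric(b$value)
  n <- nrow(a$value)
  ad_node(tape, a$value + rep(bv, each = n), function(g) {
    ad_accum(a, g)
    ad_accum(b, matrix(colSums(g), 1L))
  })
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$value * b$value, function(g) {
    ad_accum(a, g * b$value)
    ad_accum(b, g * a$value)
  })
}

ad_scale <- function(tape, a, s) {
  ad_node(tape, a$value * s, function(g) ad_accum(a, g * s))
}

ad_addconst <- function(tape, a, cmat) {
  ad_node(tape, a$value + cmat, function(g) ad_accum(a, g))
}

## ---- activations ----

ad_relu <- function(tape, a) {
  keep <- a$value > 0
  ad_node(tape, a$value * keep, function(g) ad_accum(a, g * keep))
}

# exact GELU: x * pnorm(x)
ad_gelu <- function(tape, a) {
  x <- a$value
  ph <- stats::pnorm(x)
  ad_node(tape, x * ph, function(g) ad_accum(a, g * (ph + x * stats::dnorm(x))))
}

ad_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(tape, s, function(g) ad_accum(a, g * s * (1 - s)))
}

ad_tanh <- function(tape, a) {
  th <- tanh(a$value)
  ad_node(tape, th, function(g) ad_accum(a, g * (1 - th * th)))
}

## ---- normalisation ----

# Row-wise layer normalisation with learnable gain/bias (1 x D matrices).
ad_layernorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  n <- nrow(xv)
  gam <- rep(as.numeric(gamma$value), each = n)
  mu <- rowMeans(xv)
  xc <- xv - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  val <- xhat * gam + rep(as.numeric(beta$value), each = n)
  ad_node(tape, val, function(g) {
    dxhat <- g * gam
    dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    ad_accum(x, dx)
    ad_accum(gamma, matrix(colSums(g * xhat), 1L))
    ad_accum(beta, matrix(colSums(g), 1L))
  })
}

## ---- attention ----

#' Row-wise softmax of a matrix
#' @param m numeric matrix
#' @return matrix of the same shape whose rows sum to one.
#' @export
softmax_rows <- function(m) {
  m <- m - m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m)
  e / rowSums(e)
}

# Scaled dot-product attention over `n_groups` contiguous equal-sized row
# groups of Q/K/V (each group is one image's / sequence's tokens). Caches the
# attention matrices for the backward sweep.
ad_attention <- function(tape, q, k, v, n_groups, d_k) {
  n <- nrow(q$value)
  stopifnot(n %% n_groups == 0L)
  gs <- n %/% n_groups
  scl <- 1 / sqrt(d_k)
  A <- vector("list", n_groups)
  out <- matrix(0, n, ncol(v$value))
  for (gidx in seq_len(n_groups)) {
    rows <- ((gidx - 1L) * gs + 1L):(gidx * gs)
    S <- tcrossprod(q$value[rows, , drop = FALSE], k$value[rows, , drop = FALSE]) * scl
    A[[gidx]] <- softmax_rows(S)
    out[rows, ] <- A[[gidx]] %*% v$value[rows, , drop = FALSE]
  }
  ad_node(tape, out, function(g) {
    dq <- matrix(0, n, ncol(q$value))
    dk <- matrix(0, n, ncol(k$value))
    dv <- matrix(0, n, ncol(v$value))
    for (gidx in seq_len(n_groups)) {
      rows <- ((gidx - 1L) * gs + 1L):(gidx * gs)
      Ag <- A[[gidx]]
      gg <- g[rows, , drop = FALSE]
      dv[rows, ] <- crossprod(Ag, gg)
      dA <- tcrossprod(gg, v$value[rows, , drop = FALSE])
      dS <- Ag * (dA - rowSums(dA * Ag)) * scl
      dq[rows, ] <- dS %*% k$value[rows, , drop = FALSE]
      dk[rows, ] <- crossprod(dS, q$value[rows, , drop = FALSE])
    }
    ad_accum(q, dq)
    ad_accum(k, dk)
    ad_accum(v, dv)
  })
}

## ---- structural ops ----

ad_cbind <- function(tape, nodes) {
  widths <- vapply(nodes, function(nd) ncol(nd$value), 1L)
  offs <- cumsum(c(0L, widths))
  ad_node(tape, do.call(cbind, lapply(nodes, function(nd) nd$value)), function(g) {
    for (i in seq_along(nodes)) {
      ad_accum(nodes[[i]], g[, (offs[i] + 1L):offs[i + 1L], drop = FALSE])
    }
  })
}

# Select rows (idx must be unique).
ad_rows <- function(tape, a, idx) {
  ad_node(tape, a$value[idx, , drop = FALSE], function(g) {
    gm <- matrix(0, nrow(a$value), ncol(a$value))
    gm[idx, ] <- g
    ad_accum(a, gm)
  })
}

# Select columns (idx unique).
ad_cols <- function(tape, a, idx) {
  ad_node(tape, a$value[, idx, drop = FALSE], function(g) {
    gm <- matrix(0, nrow(a$value), ncol(a$value))
    gm[, idx] <- g
    ad_accum(a, gm)
  })
}

# Prepend a shared class-token row (1 x D parameter) to each of n_groups
# contiguous token groups: (G*N) x D patches -> (G*(N+1)) x D.
ad_prepend_cls <- function(tape, patches, cls, n_groups) {
  np <- nrow(patches$value)
  stopifnot(np %% n_groups == 0L)
  N <- np %/% n_groups
  D <- ncol(patches$value)
  ntok <- N + 1L
  cls_rows <- seq.int(1L, by = ntok, length.out = n_groups)
  out <- matrix(0, n_groups * ntok, D)
  out[cls_rows, ] <- matrix(as.numeric(cls$value), n_groups, D, byrow = TRUE)
  out[-cls_rows, ] <- patches$value
  ad_node(tape, out, function(g) {
    ad_accum(cls, matrix(colSums(g[cls_rows, , drop = FALSE]), 1L))
    ad_accum(patches, g[-cls_rows, , drop = FALSE])
  })
}

# a + b tiled over groups: nrow(a) = reps * nrow(b). Used for positional
# embeddings shared across all images in a batch.
ad_add_tiled <- function(tape, a, b, reps) {
  nb <- nrow(b$value)
  stopifnot(nrow(a$value) == reps * nb)
  idx <- rep(seq_len(nb), times = reps)
  ad_node(tape, a$value + b$value[idx, , drop = FALSE], function(g) {
    ad_accum(a, g)
    ad_accum(b, rowsum(g, idx))
  })
}

# Mean over rows within each contiguous group: (G*N) x D -> G x D.
ad_group_mean <- function(tape, a, n_groups) {
  n <- nrow(a$value)
  stopifnot(n %% n_groups == 0L)
  N <- n %/% n_groups
  grp <- rep(seq_len(n_groups), each = N)
  ad_node(tape, rowsum(a$value, grp) / N, function(g) {
    ad_accum(a, g[grp, , drop = FALSE] / N)
  })
}

## ---- regularisers, losses ----

ad_dropout <- function(tape, a, p) {
  if (!tape$training || p <= 0) return(a)
  mask <- (matrix(stats::runif(length(a$value)), nrow(a$value)) >= p) / (1 - p)
  ad_node(tape, a$value * mask, function(g) ad_accum(a, g * mask))
}

ad_mse <- function(tape, pred, target) {
  d <- as.numeric(pred$value) - as.numeric(target)
  n <- length(d)
  ad_node(tape, mean(d * d), function(g) {
    ad_accum(pred, matrix((2 / n) * d * g, ncol = 1L))
  })
}

ad_sum_sq <- function(tape, a) {
  ad_node(tape, sum(a$value^2), function(g) ad_accum(a, 2 * g * a$value))
}

# weighted sum of scalar nodes
ad_scalar_sum <- function(tape, nodes, weights = rep(1, length(nodes))) {
  val <- sum(vapply(nodes, function(nd) nd$value, 1) * weights)
  ad_node(tape, val, function(g) {
    for (i in seq_along(nodes)) ad_accum(nodes[[i]], g * weights[i])
  })
}

## ---- dense layer helper ----

ad_dense <- function(tape, x, W, b, activation = c("linear", "relu", "gelu")) {
  activation <- match.arg(activation)
  out <- ad_addvec(tape, ad_matmul(tape, x, W), b)
  switch(activation,
    linear = out,
    relu = ad_relu(tape, out),
    gelu = ad_gelu(tape, out)
  )
}

## ---- Adam optimiser ----

#' Create an Adam optimiser state
#' @keywords internal
adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) array(0, dim = dim(p)))
  st$v <- lapply(params, function(p) array(0, dim = dim(p)))
  st$t <- 0L
  st$lr <- lr
  st$beta1 <- beta1
  st$beta2 <- beta2
  st$eps <- eps
  st
}

# One Adam step; returns the updated parameter list.
adam_step <- function(st, params, grads) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  c1 <- 1 - b1^st$t
  c2 <- 1 - b2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    mhat <- st$m[[nm]] / c1
    vhat <- st$v[[nm]] / c2
    params[[nm]] <- params[[nm]] - st$lr * mhat / (sqrt(vhat) + st$eps)
  }
  params
}

## ---- weight initialisation ----

# fan-in uniform (dense/conv kernels)
init_dense <- function(fan_in, fan_out) {
  lim <- 1 / sqrt(fan_in)
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

init_bias <- function(n) matrix(0, 1L, n)

# truncated normal (|x| <= 2 sd), used for token/positional embeddings
init_trunc_normal <- function(nr, nc, sd = 0.02) {
  n <- nr * nc
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  matrix(x, nr, nc)
}
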