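# Vision-transformer image encoder.
#
# An image is cut into P x P patches, each patch linearly embedded to D
# dimensions, a learnable class token is prepended and a learnable positional
# embedding added. L pre-norm transformer blocks (multi-head self-attention,
# then a GELU MLP, residual connections around both) are applied and the
# layer-normed class token is the image feature.

#' ViT shape configuration
#'
#' @param image_size input image side in pixels (square).
#' @param patch_size patch side P; must divide `image_size`.
#' @param embed_dim token width D.
#' @param depth number of transformer blocks L.
#' @param heads attention heads h; per-head width is `floor(D / h)`.
#' @param mlp_hidden MLP hidden width (default `4 * embed_dim`).
#' @param channels image channels.
#' @return list of class `vit_config`.
#' @export
vit_config <- function(image_size = 128L, patch_size = 16L, embed_dim = 128L,
                       depth = 2L, heads = 3L, mlp_hidden = 4L * embed_dim,
                       channels = 3L) {
  stopifnot(depth >= 1, heads >= 1)
  if (image_size %% patch_size != 0) {
    stop("image_size must be divisible by patch_size")
  }
  n_patches <- (image_size %/% patch_size)^2
  structure(list(image_size = as.integer(image_size),
                 patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim),
                 depth = as.integer(depth), heads = as.integer(heads),
                 mlp_hidden = as.integer(mlp_hidden),
                 channels = as.integer(channels),
                 n_patches = as.integer(n_patches),
                 d_k = as.integer(embed_dim %/% heads)),
            class = "vit_config")
}

#' Number of tokens when an image is split into patches
#'
#' With `patch_size = 1` every pixel is its own token; a 300 x 300 image then
#' yields 90,000 tokens, the combinatorial blow-up that motivates patching.
#'
#' @param height,width image size in pixels.
#' @param patch_size patch side; must divide both dimensions.
#' @return integer patch count N (class token not included).
#' @export
n_patch_tokens <- function(height, width, patch_size) {
  if (height %% patch_size != 0 || width %% patch_size != 0) {
    stop("image dimensions must be divisible by patch_size")
  }
  as.integer((height %/% patch_size) * (width %/% patch_size))
}

#' Cut an image into flattened patches (row-major order)
#'
#' @param image numeric array `H x W x C`.
#' @param patch_size patch side P.
#' @return numeric matrix `N x (P^2 C)`; patch rows ordered top-left to
#'   bottom-right, row-major.
#' @export
patchify <- function(image, patch_size) {
  h <- dim(image)[1]; w <- dim(image)[2]; ch <- dim(image)[3]
  N <- n_patch_tokens(h, w, patch_size)
  nph <- h %/% patch_size; npw <- w %/% patch_size
  out <- matrix(0, N, patch_size^2 * ch)
  k <- 0L
  for (pr in seq_len(nph)) {
    rr <- ((pr - 1L) * patch_size + 1L):(pr * patch_size)
    for (pc in seq_len(npw)) {
      cc <- ((pc - 1L) * patch_size + 1L):(pc * patch_size)
      k <- k + 1L
      out[k, ] <- as.numeric(image[rr, cc, , drop = FALSE])
    }
  }
  out
}

# stack patchified images row-wise: (n_images * N) x (P^2 C)
patchify_stack <- function(images, patch_size) {
  do.call(rbind, lapply(images, patchify, patch_size = patch_size))
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`; every softmax row sums to one.
#'
#' @param Q,K,V numeric matrices; `Q` and `K` must have `d_k` columns and
#'   `K`, `V` equal row counts.
#' @param d_k key/query width used for scaling (default `ncol(K)`).
#' @return matrix with `nrow(Q)` rows and `ncol(V)` columns.
#' @export
scaled_dot_product_attention <- function(Q, K, V, d_k = ncol(K)) {
  if (ncol(Q) != d_k || ncol(K) != d_k) {
    stop("Q and K must have d_k columns")
  }
  if (nrow(K) != nrow(V)) stop("K and V must have equal row counts")
  softmax_rows(tcrossprod(Q, K) / sqrt(d_k)) %*% V
}

#' Multi-head self-attention on a token matrix
#'
#' Each head projects the tokens to per-head Q/K/V, runs scaled dot-product
#' attention, the head outputs are concatenated and projected by `W_O`.
#'
#' @param a token matrix `n x D`.
#' @param head_params list of `h` lists with elements `Wq`, `Wk`, `Wv`
#'   (each `D x d_k`).
#' @param W_O output projection `(h d_k) x D`.
#' @param b_O optional output bias (length-D vector); default zero.
#' @return token matrix `n x D`.
#' @export
multi_head_attention <- function(a, head_params, W_O, b_O = NULL) {
  d_k <- ncol(head_params[[1]]$Wq)
  heads <- lapply(head_params, function(hp) {
    scaled_dot_product_attention(a %*% hp$Wq, a %*% hp$Wk, a %*% hp$Wv, d_k)
  })
  conc <- do.call(cbind, heads)
  if (ncol(conc) != nrow(W_O)) {
    stop("W_O row count must equal h * d_k (got ", nrow(W_O),
         ", need ", ncol(conc), ")")
  }
  out <- conc %*% W_O
  if (!is.null(b_O)) out <- sweep(out, 2L, as.numeric(b_O), "+")
  out
}

## ---- parameters ----

# one transformer block's parameter names (shared by ViT and temporal stacks)
block_param_names <- function(l, heads) {
  nm <- c(sprintf("L%d_ln1_g", l), sprintf("L%d_ln1_b", l))
  for (i in seq_len(heads)) {
    nm <- c(nm, sprintf("L%d_h%d_Wq", l, i), sprintf("L%d_h%d_Wk", l, i),
            sprintf("L%d_h%d_Wv", l, i))
  }
  c(nm, sprintf("L%d_Wo", l), sprintf("L%d_bo", l),
    sprintf("L%d_ln2_g", l), sprintf("L%d_ln2_b", l),
    sprintf("L%d_W1", l), sprintf("L%d_b1", l),
    sprintf("L%d_W2", l), sprintf("L%d_b2", l))
}

init_block <- function(D, heads, d_k, mlp_hidden, l) {
  p <- list()
  p[[sprintf("L%d_ln1_g", l)]] <- matrix(1, 1, D)
  p[[sprintf("L%d_ln1_b", l)]] <- matrix(0, 1, D)
  for (i in seq_len(heads)) {
    p[[sprintf("L%d_h%d_Wq", l, i)]] <- init_dense(D, d_k)
    p[[sprintf("L%d_h%d_Wk", l, i)]] <- init_dense(D, d_k)
    p[[sprintf("L%d_h%d_Wv", l, i)]] <- init_dense(D, d_k)
  }
  p[[sprintf("L%d_Wo", l)]] <- init_dense(heads * d_k, D)
  p[[sprintf("L%d_bo", l)]] <- init_bias(D)
  p[[sprintf("L%d_ln2_g", l)]] <- matrix(1, 1, D)
  p[[sprintf("L%d_ln2_b", l)]] <- matrix(0, 1, D)
  p[[sprintf("L%d_W1", l)]] <- init_dense(D, mlp_hidden)
  p[[sprintf("L%d_b1", l)]] <- init_bias(mlp_hidden)
  p[[sprintf("L%d_W2", l)]] <- init_dense(mlp_hidden, D)
  p[[sprintf("L%d_b2", l)]] <- init_bias(D)
  p
}

#' Initialise ViT weights
#'
#' Dense/attention projections use fan-in uniform initialisation; the class
#' token and positional embeddings use a truncated normal (sd 0.02).
#' Draws from the current RNG stream.
#'
#' @param config a [vit_config()].
#' @return named list of parameter matrices.
#' @export
vit_init <- function(config) {
  D <- config$embed_dim
  pd <- config$patch_size^2 * config$channels
  p <- list(
    E = init_dense(pd, D),
    bE = init_bias(D),
    cls = init_trunc_normal(1, D),
    Epos = init_trunc_normal(config$n_patches + 1L, D)
  )
  for (l in seq_len(config$depth)) {
    p <- c(p, init_block(D, config$heads, config$d_k, config$mlp_hidden, l))
  }
  p$lnf_g <- matrix(1, 1, D)
  p$lnf_b <- matrix(0, 1, D)
  p
}

## ---- tape forward ----

# one pre-norm transformer block over grouped tokens
block_forward <- function(tape, pn, z, l, heads, d_k, n_groups, D) {
  a <- ad_layernorm(tape, z, pn[[sprintf("L%d_ln1_g", l)]], pn[[sprintf("L%d_ln1_b", l)]])
  hd <- vector("list", heads)
  for (i in seq_len(heads)) {
    q <- ad_matmul(tape, a, pn[[sprintf("L%d_h%d_Wq", l, i)]])
    k <- ad_matmul(tape, a, pn[[sprintf("L%d_h%d_Wk", l, i)]])
    v <- ad_matmul(tape, a, pn[[sprintf("L%d_h%d_Wv", l, i)]])
    hd[[i]] <- ad_attention(tape, q, k, v, n_groups, d_k)
  }
  mh <- ad_dense(tape, ad_cbind(tape, hd),
                 pn[[sprintf("L%d_Wo", l)]], pn[[sprintf("L%d_bo", l)]])
  z <- ad_add(tape, z, mh)
  a2 <- ad_layernorm(tape, z, pn[[sprintf("L%d_ln2_g", l)]], pn[[sprintf("L%d_ln2_b", l)]])
  m <- ad_dense(tape, a2, pn[[sprintf("L%d_W1", l)]], pn[[sprintf("L%d_b1", l)]], "gelu")
  m <- ad_dense(tape, m, pn[[sprintf("L%d_W2", l)]], pn[[sprintf("L%d_b2", l)]])
  ad_add(tape, z, m)
}

# ViT forward over a stack of patchified images.
# patches_node: ((n_images * N) x P^2C) leaf; returns (n_images x D) node.
vit_forward <- function(tape, pn, patches_node, n_images, config) {
  N <- config$n_patches
  tok <- ad_dense(tape, patches_node, pn$E, pn$bE)
  z <- ad_prepend_cls(tape, tok, pn$cls, n_images)
  z <- ad_add_tiled(tape, z, pn$Epos, n_images)
  for (l in seq_len(config$depth)) {
    z <- block_forward(tape, pn, z, l, config$heads, config$d_k, n_images,
                       config$embed_dim)
  }
  cls_rows <- seq.int(1L, by = N + 1L, length.out = n_images)
  y <- ad_rows(tape, z, cls_rows)
  ad_layernorm(tape, y, pn$lnf_g, pn$lnf_b)
}

#' Apply one ViT transformer block to a token matrix
#'
#' Pre-norm block: `z' = MultiHead(LN(z)) + z; z_out = MLP(LN(z')) + z'` with
#' a GELU MLP. Exposed mainly for inspection and testing; training uses the
#' batched internal path.
#'
#' @param z token matrix `(N+1) x D`.
#' @param params ViT parameter list from [vit_init()].
#' @param layer 1-based block index.
#' @param config the [vit_config()].
#' @return transformed token matrix.
#' @export
vit_layer <- function(z, params, layer, config) {
  tape <- ad_tape(training = FALSE)
  pn <- ad_leaves(tape, params)
  zn <- ad_leaf(tape, z)
  block_forward(tape, pn, zn, layer, config$heads, config$d_k, 1L,
                config$embed_dim)$value
}

#' Embed an image as a patch-token sequence
#'
#' `z_0 = [class; x_p^1 E; ...; x_p^N E] + E_pos`, patches in row-major order.
#'
#' @param image numeric array `H x W x C`.
#' @param params ViT parameters ([vit_init()]).
#' @param config the [vit_config()].
#' @return token matrix `(N+1) x D` with the class token in row 1.
#' @export
patchify_embed <- function(image, params, config) {
  pm <- patchify(image, config$patch_size)
  tok <- sweep(pm %*% params$E, 2L, as.numeric(params$bE), "+")
  rbind(params$cls, tok) + params$Epos
}

#' Encode an image to a D-dimensional ViT feature
#'
#' Runs the full ViT forward pass and returns the layer-normed class token
#' after the last block. Deterministic given weights.
#'
#' @param image numeric array `H x W x C` matching the config.
#' @param params ViT parameters ([vit_init()]).
#' @param config the [vit_config()].
#' @return numeric feature vector of length `embed_dim`.
#' @export
vit_encode <- function(image, params, config) {
  tape <- ad_tape(training = FALSE)
  pn <- ad_leaves(tape, params)
  patches <- ad_leaf(tape, patchify(image, config$patch_size))
  as.numeric(vit_forward(tape, pn, patches, 1L, config)$value)
}
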