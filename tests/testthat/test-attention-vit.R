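# Attention primitives and the ViT encoder, checked against independent
# loop-based oracles and structural identities.

# brute-force oracle: per-row softmax over explicit double loops
sdpa_oracle <- function(Q, K, V, d_k) {
  out <- matrix(0, nrow(Q), ncol(V))
  for (i in seq_len(nrow(Q))) {
    s <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d_k)
    w <- exp(s - max(s)); w <- w / sum(w)
    for (j in seq_len(nrow(K))) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

test_that("scaled dot-product attention matches the loop oracle and its limits", {
  set.seed(1)
  for (rep in 1:20) {
    Q <- matrix(rnorm(32), 4, 8); K <- matrix(rnorm(32), 4, 8)
    V <- matrix(rnorm(24), 4, 6)
    expect_equal(scaled_dot_product_attention(Q, K, V, 8),
                 sdpa_oracle(Q, K, V, 8), tolerance = 1e-6)
  }
  # single token: softmax of a scalar is 1, output is V
  q <- matrix(rnorm(8), 1); k <- matrix(rnorm(8), 1); v <- matrix(rnorm(3), 1)
  expect_equal(scaled_dot_product_attention(q, k, v, 8), v)
  # zero queries: uniform attention, every row the column mean of V
  V <- matrix(rnorm(12), 4, 3)
  out <- scaled_dot_product_attention(matrix(0, 4, 8), matrix(rnorm(32), 4, 8), V, 8)
  for (i in 1:4) expect_equal(out[i, ], colMeans(V), tolerance = 1e-12)
  expect_error(scaled_dot_product_attention(matrix(0, 2, 3), matrix(0, 2, 4),
                                            matrix(0, 2, 4), 4), "d_k")
  expect_error(scaled_dot_product_attention(matrix(0, 2, 4), matrix(0, 3, 4),
                                            matrix(0, 2, 4), 4), "row counts")
})

test_that("multi-head attention equals the head-by-head oracle", {
  set.seed(2)
  D <- 6; d_k <- 2; h <- 3
  a <- matrix(rnorm(5 * D), 5, D)
  hp <- lapply(seq_len(h), function(i) {
    list(Wq = matrix(rnorm(D * d_k), D), Wk = matrix(rnorm(D * d_k), D),
         Wv = matrix(rnorm(D * d_k), D))
  })
  W_O <- matrix(rnorm(h * d_k * D), h * d_k, D)
  got <- multi_head_attention(a, hp, W_O)
  expect_equal(dim(got), c(5L, D))
  oracle <- do.call(cbind, lapply(hp, function(p) {
    sdpa_oracle(a %*% p$Wq, a %*% p$Wk, a %*% p$Wv, d_k)
  })) %*% W_O
  expect_equal(got, oracle, tolerance = 1e-6)
  # h = 1 with identity output projection reduces to plain attention
  expect_equal(multi_head_attention(a, hp[1], diag(d_k)),
               scaled_dot_product_attention(a %*% hp[[1]]$Wq, a %*% hp[[1]]$Wk,
                                            a %*% hp[[1]]$Wv, d_k),
               tolerance = 1e-12)
  expect_error(multi_head_attention(a, hp, matrix(0, 5, D)), "W_O")
})

test_that("patch arithmetic matches the stated token counts", {
  expect_equal(n_patch_tokens(128, 128, 16), 64L)
  # pixels-as-tokens: a 300x300 image is 90,000 tokens
  expect_equal(n_patch_tokens(300, 300, 1), 90000L)
  expect_error(n_patch_tokens(100, 100, 16), "divisible")

  cfg <- vit_config()
  set.seed(3)
  p <- vit_init(cfg)
  img <- rand_image(128, seed = 3)
  z0 <- patchify_embed(img, p, cfg)
  expect_equal(dim(z0), c(65L, 128L))

  # zero image with zero positional embedding: all patch tokens identical
  p0 <- p
  p0$Epos <- p0$Epos * 0
  z <- patchify_embed(array(0, c(128, 128, 3)), p0, cfg)
  expect_equal(max(apply(z[-1, ], 2, function(col) diff(range(col)))), 0)
})

test_that("patchify is row-major and lossless", {
  img <- rand_image(32, seed = 9)
  pm <- patchify(img, 16)
  expect_equal(dim(pm), c(4L, 16 * 16 * 3))
  expect_equal(pm[1, ], as.numeric(img[1:16, 1:16, ]))
  expect_equal(pm[2, ], as.numeric(img[1:16, 17:32, ]))  # row-major order
  expect_equal(pm[3, ], as.numeric(img[17:32, 1:16, ]))
})

test_that("a zero-weight ViT block is an exact identity", {
  cfg <- tiny_vit_cfg()
  set.seed(4)
  p <- vit_init(cfg)
  for (nm in grep("^L1_(h|W|b)", names(p), value = TRUE)) p[[nm]] <- p[[nm]] * 0
  z <- matrix(rnorm(5 * cfg$embed_dim), 5)
  expect_equal(vit_layer(z, p, 1L, cfg), z, tolerance = 1e-12)
})

test_that("vit_layer matches a step-by-step scripted oracle", {
  cfg <- tiny_vit_cfg(D = 6L, heads = 2L)
  set.seed(5)
  p <- vit_init(cfg)
  z <- matrix(rnorm(3 * 6), 3, 6)
  ln <- function(x, g, b, eps = 1e-5) {
    t(apply(x, 1, function(r) {
      (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps)
    })) * rep(as.numeric(g), each = nrow(x)) + rep(as.numeric(b), each = nrow(x))
  }
  gelu <- function(x) x * pnorm(x)
  a <- ln(z, p$L1_ln1_g, p$L1_ln1_b)
  heads <- lapply(1:2, function(i) {
    sdpa_oracle(a %*% p[[sprintf("L1_h%d_Wq", i)]],
                a %*% p[[sprintf("L1_h%d_Wk", i)]],
                a %*% p[[sprintf("L1_h%d_Wv", i)]], cfg$d_k)
  })
  zp <- z + sweep(do.call(cbind, heads) %*% p$L1_Wo, 2, as.numeric(p$L1_bo), "+")
  a2 <- ln(zp, p$L1_ln2_g, p$L1_ln2_b)
  mlp <- gelu(sweep(a2 %*% p$L1_W1, 2, as.numeric(p$L1_b1), "+")) %*% p$L1_W2
  oracle <- zp + sweep(mlp, 2, as.numeric(p$L1_b2), "+")
  expect_equal(vit_layer(z, p, 1L, cfg), oracle, tolerance = 1e-6)
})

test_that("vit_encode has the contract shape, determinism and PE-controlled symmetry", {
  cfg <- tiny_vit_cfg(size = 64L, D = 10L)
  set.seed(6)
  p <- vit_init(cfg)
  img <- rand_image(64, seed = 6)
  f1 <- vit_encode(img, p, cfg)
  expect_length(f1, 10L)
  expect_identical(f1, vit_encode(img, p, cfg))

  # permute patches of the image (swap two 16x16 blocks)
  img_perm <- img
  img_perm[1:16, 1:16, ] <- img[1:16, 17:32, ]
  img_perm[1:16, 17:32, ] <- img[1:16, 1:16, ]
  # with zero positional embeddings the class feature is permutation-invariant
  p0 <- p
  p0$Epos <- p0$Epos * 0
  expect_equal(vit_encode(img, p0, cfg), vit_encode(img_perm, p0, cfg),
               tolerance = 1e-10)
  # with (random, nonzero) positional embeddings it is not
  expect_gt(max(abs(vit_encode(img, p, cfg) - vit_encode(img_perm, p, cfg))), 1e-6)
})

test_that("attention rows always sum to one across a full forward pass", {
  set.seed(7)
  for (rep in 1:10) {
    m <- matrix(rnorm(40, sd = 3), 5, 8)
    sm <- softmax_rows(m)
    expect_equal(rowSums(sm), rep(1, 5), tolerance = 1e-6)
    expect_true(all(sm >= 0))
  }
})
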