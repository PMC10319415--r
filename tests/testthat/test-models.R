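# Model assembly: seed branch, fusion, the proposed forward pass, parameter
# accounting, and the baseline zoo.

test_that("encode_seed has the contract shape and distinguishes combos", {
  set.seed(1)
  sp <- yieldformer:::seed_init(10L)
  expect_length(encode_seed(3L, sp), 16L)
  expect_equal(encode_seed(3L, zero_params(sp)), rep(0, 16))
  distinct <- vapply(1:20, function(i) {
    set.seed(100 + i)
    p <- yieldformer:::seed_init(10L)
    !isTRUE(all.equal(encode_seed(2L, p), encode_seed(7L, p)))
  }, TRUE)
  expect_true(all(distinct))
  expect_error(encode_seed(10L, sp), "range")
  expect_error(encode_seed(-1L, sp), "range")
})

test_that("fuse_features honours Hadamard identities and matches a hand-composed oracle", {
  tcfg <- tiny_temporal_cfg()
  set.seed(2)
  tp <- temporal_init(tcfg)
  hp <- yieldformer:::head_init(6L + 4L, dims = c(5L, 5L))
  fp <- matrix(rnorm(24), 3, 8)
  fs <- matrix(rnorm(24), 3, 8)
  fseed <- rnorm(4)

  # multiplicative identity: all-ones soil stream leaves the plant stream
  expect_equal(fuse_features(fp, matrix(1, 3, 8), fseed, tp, tcfg, hp),
               fuse_features(matrix(1, 3, 8), fp, fseed, tp, tcfg, hp))
  # annihilation: zero plant stream fuses to the zero sequence
  expect_equal(fuse_features(matrix(0, 3, 8), fs, fseed, tp, tcfg, hp),
               fuse_features(matrix(0, 3, 8), matrix(1, 3, 8), fseed, tp, tcfg, hp))

  # independent composition of the three sub-operations
  relu <- function(x) pmax(x, 0)
  v <- encode_sequence(fp * fs, tp, tcfg)
  x <- c(v, fseed)
  h <- relu(x %*% hp$h1_W + as.numeric(hp$h1_b))
  h <- relu(h %*% hp$h2_W + as.numeric(hp$h2_b))
  oracle <- as.numeric(h %*% hp$hout_W + as.numeric(hp$hout_b))
  expect_equal(fuse_features(fp, fs, fseed, tp, tcfg, hp), oracle,
               tolerance = 1e-6)
  expect_error(fuse_features(fp, fs[1:2, ], fseed, tp, tcfg, hp), "aligned")
})

test_that("forward_proposed is deterministic, finite and seed-sensitive", {
  ds <- tiny_dataset(4, image_size = 64L, dir_tag = "fwd")
  recs <- load_records(ds, image_size = 64L)
  model <- build_model("proposed", preset = "small", rng_seed = 3L)
  phi1 <- forward_proposed(recs[[1]], model)
  expect_true(is.finite(phi1) && length(phi1) == 1L)
  expect_identical(phi1, forward_proposed(recs[[1]], model))
  # counterfactual seed flip changes the prediction (nonzero seed weights)
  rec2 <- recs[[1]]
  rec2$combo_index <- (rec2$combo_index + 1L) %% model$n_combos
  expect_false(forward_proposed(rec2, model) == phi1)
  # missing timestamp image is a data error naming the plot
  bad <- recs[[2]]
  bad$images[[2]] <- NULL
  expect_error(forward_proposed(bad, model), "missing a timestamp")
})

test_that("parameter counts match a shape-walking oracle", {
  model <- build_model("proposed", preset = "small", n_combos = 51L, rng_seed = 1L)
  vc <- model$vit_cfg
  tc <- model$temporal_cfg
  block_n <- function(D, h, dk, mlp) {
    2 * D +                      # ln1
      3 * h * D * dk +           # per-head Q/K/V
      h * dk * D + D +           # output projection + bias
      2 * D +                    # ln2
      D * mlp + mlp + mlp * D + D
  }
  vit_n <- (vc$patch_size^2 * 3) * vc$embed_dim + vc$embed_dim +  # E, bE
    vc$embed_dim +                                                # cls
    (vc$n_patches + 1) * vc$embed_dim +                           # Epos
    vc$depth * block_n(vc$embed_dim, vc$heads, vc$d_k, vc$mlp_hidden) +
    2 * vc$embed_dim                                              # final LN
  temp_n <- tc$d_model^2 + tc$d_model +
    tc$depth * block_n(tc$d_model, tc$heads, tc$d_k, tc$mlp_hidden) +
    tc$d_model * tc$out_dim + tc$out_dim
  seed_n <- 51 * 16 + 16 + 16 * 16 + 16 + 16 * 16 + 16
  hd <- c(tc$out_dim + 16L, model$head_dims)
  head_n <- sum(hd[-length(hd)] * hd[-1] + hd[-1]) + hd[length(hd)] * 1 + 1
  expect_equal(count_parameters(model), 2 * vit_n + temp_n + seed_n + head_n)
})

test_that("every baseline produces a finite scalar under the shared contract", {
  ds <- tiny_dataset(2, image_size = 64L, dir_tag = "base")
  recs <- load_records(ds, image_size = 64L)
  for (kind in c("cnn_lr", "cnn_lstm", "vit_lstm", "vit_t")) {
    model <- build_baseline(kind, preset = "small", rng_seed = 4L)
    preds <- predict_yield(model, recs)
    expect_length(preds, 2L)
    expect_true(all(is.finite(preds)), label = kind)
  }
  expect_error(build_baseline("proposed"), "unknown baseline")
  expect_error(build_model("resnet"), "arg")
})

test_that("the ablated model drops the seed branch and narrows the head", {
  m <- build_model("proposed", preset = "small", use_seed = FALSE, rng_seed = 5L)
  expect_false(any(startsWith(names(m$params), "seed.")))
  expect_equal(nrow(m$params[["head.h1_W"]]), m$temporal_cfg$out_dim)
  m2 <- build_model("proposed", preset = "small", use_seed = TRUE, rng_seed = 5L)
  expect_equal(nrow(m2$params[["head.h1_W"]]), m2$temporal_cfg$out_dim + 16L)
})

test_that("vit_t equals the fusion pipeline with a unit soil stream", {
  ds <- tiny_dataset(2, image_size = 64L, dir_tag = "vitt")
  recs <- load_records(ds, image_size = 64L)
  model <- build_baseline("vit_t", preset = "small", rng_seed = 6L)
  preds <- predict_yield(model, recs)
  vp <- yieldformer:::sub_list(model$params, "vit")
  tp <- yieldformer:::sub_list(model$params, "temporal")
  hp <- yieldformer:::sub_list(model$params, "head")
  for (i in seq_along(recs)) {
    fv <- do.call(rbind, lapply(recs[[i]]$images, vit_encode, params = vp,
                                config = model$vit_cfg))
    manual <- fuse_features(fv, matrix(1, nrow(fv), ncol(fv)),
                            encode_seed(recs[[i]]$combo_index, model),
                            tp, model$temporal_cfg, hp)
    expect_equal(preds[i], manual * model$y_scale + model$y_center,
                 tolerance = 1e-8)
  }
})

test_that("CNN-LR's L2 penalty trades training fit for weight shrinkage", {
  ds <- tiny_dataset(8, image_size = 64L, dir_tag = "l2",
                     yield_params = yield_model_params())
  recs <- load_records(ds, image_size = 64L)
  train_mse <- function(l2) {
    m <- build_baseline("cnn_lr", preset = "small", l2 = l2, rng_seed = 7L)
    cfg <- train_config(max_epochs = 6L, batch_size = 4L, rng_seed = 7L)
    m <- train_model(m, recs, recs, config = cfg)
    mean((predict_yield(m, recs) - vapply(recs, `[[`, 1, "yield"))^2)
  }
  expect_lt(train_mse(0), train_mse(50))
})
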