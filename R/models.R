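# Model zoo: the proposed wide-deep dual-ViT model and the four baselines.
#
# All five models share one contract: build_model() constructs weights,
# prepare_model_data() turns plot records into the tensors the architecture
# consumes, model_forward_batch() builds the tape program for a mini-batch,
# and predict_yield() / train_model() (train.R) treat every kind uniformly.
#
# The proposed architecture implements phi = Phi((f_plant . f_soil) + f_seed)
# with "." as the element-wise (Hadamard) product of the two 128-d stream
# features per timestamp and "+" as concatenation of the temporal image
# representation with the 16-d seed embedding, feeding the shared head.

model_kinds <- c("proposed", "cnn_lr", "cnn_lstm", "vit_lstm", "vit_t")

prefix_params <- function(p, prefix) {
  names(p) <- paste0(prefix, ".", names(p))
  p
}

sub_nodes <- function(pn, prefix) {
  pre <- paste0(prefix, ".")
  sel <- startsWith(names(pn), pre)
  out <- pn[sel]
  names(out) <- substring(names(out), nchar(pre) + 1L)
  out
}

one_hot <- function(idx, n_classes) {
  if (any(idx < 0 | idx >= n_classes)) stop("combo index out of range [0, n_combos)")
  m <- matrix(0, length(idx), n_classes)
  m[cbind(seq_along(idx), idx + 1L)] <- 1
  m
}

# seed-information branch parameters: one-hot -> three dense layers of 16
seed_init <- function(n_combos, dims = c(16L, 16L, 16L)) {
  p <- list()
  fin <- n_combos
  for (i in seq_along(dims)) {
    p[[sprintf("s%d_W", i)]] <- init_dense(fin, dims[i])
    p[[sprintf("s%d_b", i)]] <- init_bias(dims[i])
    fin <- dims[i]
  }
  p
}

seed_forward <- function(tape, pn, onehot_node, dropout) {
  h <- onehot_node
  i <- 1L
  while (!is.null(pn[[sprintf("s%d_W", i)]])) {
    h <- ad_dense(tape, h, pn[[sprintf("s%d_W", i)]], pn[[sprintf("s%d_b", i)]], "relu")
    h <- ad_dropout(tape, h, dropout)
    i <- i + 1L
  }
  h
}

# shared regression head: dense layers (ReLU + dropout) then one linear unit
head_init <- function(input_dim, dims = c(128L, 128L, 128L)) {
  p <- list()
  fin <- input_dim
  for (i in seq_along(dims)) {
    p[[sprintf("h%d_W", i)]] <- init_dense(fin, dims[i])
    p[[sprintf("h%d_b", i)]] <- init_bias(dims[i])
    fin <- dims[i]
  }
  p$hout_W <- init_dense(fin, 1L)
  p$hout_b <- init_bias(1L)
  p
}

head_forward <- function(tape, pn, x, dropout) {
  h <- x
  i <- 1L
  while (!is.null(pn[[sprintf("h%d_W", i)]])) {
    h <- ad_dense(tape, h, pn[[sprintf("h%d_W", i)]], pn[[sprintf("h%d_b", i)]], "relu")
    h <- ad_dropout(tape, h, dropout)
    i <- i + 1L
  }
  ad_dense(tape, h, pn$hout_W, pn$hout_b)
}

#' Build a yield-prediction model
#'
#' Constructs weights for the proposed dual-ViT wide-deep model or one of the
#' four baselines (`cnn_lr`, `cnn_lstm`, `vit_lstm`, `vit_t`). The `"published"`
#' preset uses the published shapes (128 x 128 x 3 input, ViT with two 3-head
#' attention blocks and D = 128, temporal transformer with three 5-head
#' blocks, VGG-16 conv backbone, seed branch 3 x 16, head 3 x 128 + 1). The
#' `"small"` preset shrinks every component (64 x 64 input, D = 32 ViT, one
#' block per stack, 4-conv-block backbone) for desk-scale training runs.
#'
#' @param kind one of `"proposed"`, `"cnn_lr"`, `"cnn_lstm"`, `"vit_lstm"`,
#'   `"vit_t"`.
#' @param preset `"published"` or `"small"`.
#' @param n_combos number of seed combinations (one-hot width).
#' @param n_timestamps images per plot.
#' @param use_seed include the seed-information branch? (`FALSE` gives the
#'   "without seed information" ablation; the head then sees only the image
#'   representation.)
#' @param dropout dropout rate on dense layers (0.25 as published).
#' @param l2 L2 penalty weight on the CNN-LR regression layer.
#' @param rng_seed optional integer; fixes the weight initialisation.
#' @param image_size optional override of the preset's input side (must stay
#'   divisible by the patch size and by the conv backbone's pooling depth).
#' @return object of class `yf_model`.
#' @export
build_model <- function(kind = model_kinds, preset = c("published", "small"),
                        n_combos = 51L, n_timestamps = 3L, use_seed = TRUE,
                        dropout = 0.25, l2 = 1e-3, rng_seed = NULL,
                        image_size = NULL) {
  kind <- match.arg(kind)
  preset <- match.arg(preset)
  if (preset == "published") {
    vit_cfg <- vit_config(image_size = 128L, patch_size = 16L, embed_dim = 128L,
                          depth = 2L, heads = 3L)
    tconf <- temporal_config(d_model = 128L, depth = 3L, heads = 5L, out_dim = 128L)
    cconf <- conv_config("vgg16", image_size = 128L)
    head_dims <- c(128L, 128L, 128L)
  } else {
    vit_cfg <- vit_config(image_size = 64L, patch_size = 16L, embed_dim = 32L,
                          depth = 1L, heads = 2L, mlp_hidden = 64L)
    tconf <- temporal_config(d_model = 32L, depth = 1L, heads = 2L,
                             out_dim = 48L, mlp_hidden = 64L)
    cconf <- conv_config("small", image_size = 64L)
    head_dims <- c(64L, 64L, 64L)
  }
  if (!is.null(image_size)) {
    vit_cfg <- vit_config(image_size = image_size, patch_size = vit_cfg$patch_size,
                          embed_dim = vit_cfg$embed_dim, depth = vit_cfg$depth,
                          heads = vit_cfg$heads, mlp_hidden = vit_cfg$mlp_hidden)
    if (kind %in% c("cnn_lr", "cnn_lstm")) {
      cconf <- conv_config(cconf$kind, image_size = image_size,
                           fc_dims = cconf$fc_dims)
    }
  }
  builder <- function() {
    params <- list()
    img_feat <- NULL
    if (kind %in% c("proposed", "vit_t", "vit_lstm")) {
      if (kind == "proposed") {
        params <- c(params, prefix_params(vit_init(vit_cfg), "plant"),
                    prefix_params(vit_init(vit_cfg), "soil"))
      } else {
        params <- c(params, prefix_params(vit_init(vit_cfg), "vit"))
      }
      stream_dim <- vit_cfg$embed_dim
    } else {
      params <- c(params, prefix_params(conv_init(cconf), "conv"))
      stream_dim <- cconf$out_dim
    }
    lconf <- NULL
    if (kind %in% c("proposed", "vit_t")) {
      tc <- tconf
      tc$d_model <- as.integer(stream_dim)
      tc$d_k <- as.integer(stream_dim %/% tc$heads)
      params <- c(params, prefix_params(temporal_init(tc), "temporal"))
      tconf <<- tc
      img_feat <- tc$out_dim
    } else if (kind %in% c("cnn_lstm", "vit_lstm")) {
      lconf <- lstm_config(input_dim = stream_dim, hidden = 64L, layers = 2L)
      params <- c(params, prefix_params(lstm_init(lconf), "lstm"))
      img_feat <- lconf$out_dim
    } else { # cnn_lr
      lr_in <- n_timestamps * stream_dim
      params <- c(params, prefix_params(
        list(W = init_dense(lr_in, 256L), b = init_bias(256L)), "lr"))
      img_feat <- 256L
    }
    if (use_seed) params <- c(params, prefix_params(seed_init(n_combos), "seed"))
    head_in <- img_feat + if (use_seed) 16L else 0L
    params <- c(params, prefix_params(head_init(head_in, head_dims), "head"))
    list(params = params, lconf = lconf)
  }
  built <- if (is.null(rng_seed)) builder() else with_seed(rng_seed, builder())
  structure(list(kind = kind, preset = preset, n_combos = as.integer(n_combos),
                 n_timestamps = as.integer(n_timestamps),
                 use_seed = isTRUE(use_seed), dropout = dropout, l2 = l2,
                 vit_cfg = vit_cfg, temporal_cfg = tconf, conv_cfg = cconf,
                 lstm_cfg = built$lconf, head_dims = head_dims,
                 params = built$params, trained = FALSE,
                 y_center = 0, y_scale = 1),
            class = "yf_model")
}

#' Build one of the baseline architectures
#'
#' Thin wrapper over [build_model()] restricted to the four baseline names.
#'
#' @param name `"cnn_lr"`, `"cnn_lstm"`, `"vit_lstm"` or `"vit_t"`.
#' @param ... forwarded to [build_model()].
#' @return a `yf_model`.
#' @export
build_baseline <- function(name, ...) {
  if (!name %in% setdiff(model_kinds, "proposed")) {
    stop("unknown baseline name: ", name)
  }
  build_model(kind = name, ...)
}

#' Count trainable parameters of a model
#' @param model a `yf_model`.
#' @return integer total number of scalar parameters.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, 1L))
}

#' Architecture dump for shape audits
#' @param model a `yf_model`.
#' @return data.frame with one row per parameter tensor: `name`, `rows`,
#'   `cols`, `n`.
#' @export
model_shapes <- function(model) {
  data.frame(name = names(model$params),
             rows = vapply(model$params, nrow, 1L),
             cols = vapply(model$params, ncol, 1L),
             n = vapply(model$params, length, 1L),
             row.names = NULL)
}

#' Encode a seed combination to its 16-d embedding
#'
#' One-hot encodes the combination index and applies the three ReLU dense
#' layers of the seed branch (no dropout at inference).
#'
#' @param combo_index 0-based combination index.
#' @param model a `yf_model` built with `use_seed = TRUE` (or a bare named
#'   list of seed-branch parameters `s1_W, s1_b, ...`).
#' @return numeric vector of length 16.
#' @export
encode_seed <- function(combo_index, model) {
  params <- if (inherits(model, "yf_model")) {
    if (!model$use_seed) stop("model has no seed branch")
    sub_list(model$params, "seed")
  } else {
    model
  }
  n_combos <- nrow(params$s1_W)
  if (combo_index < 0 || combo_index >= n_combos) {
    stop("combo_index out of range [0, ", n_combos, ")")
  }
  tape <- ad_tape(training = FALSE)
  pn <- ad_leaves(tape, params)
  oh <- ad_leaf(tape, one_hot(combo_index, n_combos))
  as.numeric(seed_forward(tape, pn, oh, dropout = 0)$value)
}

sub_list <- function(p, prefix) {
  pre <- paste0(prefix, ".")
  sel <- startsWith(names(p), pre)
  out <- p[sel]
  names(out) <- substring(names(out), nchar(pre) + 1L)
  out
}

#' Fuse plant/soil feature sequences and a seed embedding into a yield
#'
#' Per-timestamp Hadamard product of the two stream features, temporal
#' encoding of the fused sequence, concatenation with the seed embedding and
#' the shared regression head.
#'
#' @param f_plant_seq,f_soil_seq numeric matrices `T x D`, timestamp-aligned.
#' @param f_seed numeric seed embedding (may be `NULL` for the no-seed
#'   ablation).
#' @param temporal_params,temporal_cfg temporal-transformer weights/config.
#' @param head_params regression-head weights (`h1_W`, ..., `hout_b`).
#' @return predicted yield (scalar, standardised units of the head).
#' @export
fuse_features <- function(f_plant_seq, f_soil_seq, f_seed, temporal_params,
                          temporal_cfg, head_params) {
  if (is.null(dim(f_plant_seq))) f_plant_seq <- matrix(f_plant_seq, nrow = 1L)
  if (is.null(dim(f_soil_seq))) f_soil_seq <- matrix(f_soil_seq, nrow = 1L)
  if (!all(dim(f_plant_seq) == dim(f_soil_seq))) {
    stop("plant and soil feature sequences must be timestamp-aligned")
  }
  m <- f_plant_seq * f_soil_seq
  v <- encode_sequence(m, temporal_params, temporal_cfg)
  x <- c(v, f_seed)
  tape <- ad_tape(training = FALSE)
  pn <- ad_leaves(tape, head_params)
  xn <- ad_leaf(tape, matrix(x, nrow = 1L))
  as.numeric(head_forward(tape, pn, xn, dropout = 0)$value)
}

## ---- per-plot forward (reference path) ----

# image branch of the proposed model for one plot: list of T images ->
# temporal representation (length out_dim)
image_branch_proposed <- function(model, images) {
  cfg <- model$vit_cfg
  T_len <- length(images)
  segs <- lapply(images, segment_plant_soil)
  tape <- ad_tape(training = FALSE)
  pn <- ad_leaves(tape, model$params)
  pp <- ad_leaf(tape, patchify_stack(lapply(segs, `[[`, "plant_image"), cfg$patch_size))
  sp <- ad_leaf(tape, patchify_stack(lapply(segs, `[[`, "soil_image"), cfg$patch_size))
  fp <- vit_forward(tape, sub_nodes(pn, "plant"), pp, T_len, cfg)
  fs <- vit_forward(tape, sub_nodes(pn, "soil"), sp, T_len, cfg)
  m <- ad_mul(tape, fp, fs)
  v <- temporal_forward(tape, sub_nodes(pn, "temporal"), m, 1L, T_len,
                        model$temporal_cfg)
  as.numeric(v$value)
}

# head of the proposed model given the image representation and a combo index
head_from_branch <- function(model, v, combo_index) {
  tape <- ad_tape(training = FALSE)
  pn <- ad_leaves(tape, model$params)
  xs <- list(ad_leaf(tape, matrix(v, nrow = 1L)))
  if (model$use_seed) {
    oh <- ad_leaf(tape, one_hot(combo_index, model$n_combos))
    xs <- c(xs, list(seed_forward(tape, sub_nodes(pn, "seed"), oh, dropout = 0)))
  }
  x <- if (length(xs) > 1L) ad_cbind(tape, xs) else xs[[1L]]
  raw <- as.numeric(head_forward(tape, sub_nodes(pn, "head"), x, dropout = 0)$value)
  raw * model$y_scale + model$y_center
}

#' Forward pass of the proposed model on one plot record
#'
#' Segments each image into plant and soil streams, encodes both with the
#' stream ViTs at every timestamp, fuses and summarises them with the
#' temporal transformer, and applies the seed branch and regression head.
#'
#' @param record a plot record: list with `images` (list of `H x W x 3`
#'   arrays in acquisition order), `combo_index`, and optionally `plot_id`.
#' @param model a proposed-kind `yf_model`.
#' @return predicted yield in kg/ha (a finite scalar); deterministic given
#'   weights.
#' @export
forward_proposed <- function(record, model) {
  stopifnot(inherits(model, "yf_model"), model$kind == "proposed")
  if (length(record$images) != model$n_timestamps ||
      any(vapply(record$images, is.null, TRUE))) {
    stop("plot ", record$plot_id %||% "?", " is missing a timestamp image")
  }
  v <- image_branch_proposed(model, record$images)
  head_from_branch(model, v, record$combo_index)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- batched data preparation and forward ----

#' Prepare plot records for a model's batched forward pass
#'
#' Performs the per-record work that does not depend on the weights once:
#' plant/soil segmentation (proposed), patchification (ViT streams), one-hot
#' seed encoding, and target extraction.
#'
#' @param model a `yf_model`.
#' @param records list of plot records (`images`, `combo_index`, `yield`).
#' @return opaque list consumed by the training/prediction routines.
#' @export
prepare_model_data <- function(model, records) {
  n <- length(records)
  T_len <- model$n_timestamps
  y <- vapply(records, function(r) r$yield %||% NA_real_, 1)
  oh <- one_hot(vapply(records, `[[`, 1, "combo_index"), model$n_combos)
  out <- list(n = n, T_len = T_len, y = y, onehot = oh,
              combo_index = vapply(records, `[[`, 1L, "combo_index"))
  ps <- model$vit_cfg$patch_size
  if (model$kind == "proposed") {
    plant <- vector("list", n * T_len)
    soil <- vector("list", n * T_len)
    k <- 0L
    for (r in records) {
      for (img in r$images) {
        sg <- segment_plant_soil(img)
        k <- k + 1L
        plant[[k]] <- patchify(sg$plant_image, ps)
        soil[[k]] <- patchify(sg$soil_image, ps)
      }
    }
    out$plant_patches <- do.call(rbind, plant)
    out$soil_patches <- do.call(rbind, soil)
    out$rows_per_plot <- T_len * (model$vit_cfg$n_patches)
  } else if (model$kind %in% c("vit_t", "vit_lstm")) {
    out$patches <- do.call(rbind, lapply(records, function(r) {
      patchify_stack(r$images, ps)
    }))
    out$rows_per_plot <- T_len * model$vit_cfg$n_patches
  } else {
    out$images <- lapply(records, `[[`, "images")
  }
  out
}

# rows of the stacked patch matrix belonging to plots `idx`
patch_rows <- function(idx, rows_per_plot) {
  as.integer(outer(seq_len(rows_per_plot), (idx - 1L) * rows_per_plot, "+"))
}

# batched forward for any model kind; returns the (B x 1) prediction node in
# standardised target units. `extra` collects auxiliary penalty nodes.
model_forward_batch <- function(tape, pn, model, data, idx, training) {
  B <- length(idx)
  T_len <- data$T_len
  dropout <- if (training) model$dropout else 0
  oh_node <- ad_leaf(tape, data$onehot[idx, , drop = FALSE])
  penalty <- NULL
  if (model$kind == "proposed") {
    rows <- patch_rows(idx, data$rows_per_plot)
    pp <- ad_leaf(tape, data$plant_patches[rows, , drop = FALSE])
    sp <- ad_leaf(tape, data$soil_patches[rows, , drop = FALSE])
    fp <- vit_forward(tape, sub_nodes(pn, "plant"), pp, B * T_len, model$vit_cfg)
    fs <- vit_forward(tape, sub_nodes(pn, "soil"), sp, B * T_len, model$vit_cfg)
    m <- ad_mul(tape, fp, fs)
    img <- temporal_forward(tape, sub_nodes(pn, "temporal"), m, B, T_len,
                            model$temporal_cfg)
  } else if (model$kind == "vit_t") {
    rows <- patch_rows(idx, data$rows_per_plot)
    pv <- ad_leaf(tape, data$patches[rows, , drop = FALSE])
    fv <- vit_forward(tape, sub_nodes(pn, "vit"), pv, B * T_len, model$vit_cfg)
    img <- temporal_forward(tape, sub_nodes(pn, "temporal"), fv, B, T_len,
                            model$temporal_cfg)
  } else if (model$kind == "vit_lstm") {
    rows <- patch_rows(idx, data$rows_per_plot)
    pv <- ad_leaf(tape, data$patches[rows, , drop = FALSE])
    fv <- vit_forward(tape, sub_nodes(pn, "vit"), pv, B * T_len, model$vit_cfg)
    xs <- lapply(seq_len(T_len), function(t) {
      ad_rows(tape, fv, seq.int(t, by = T_len, length.out = B))
    })
    img <- bilstm_forward(tape, sub_nodes(pn, "lstm"), xs, model$lstm_cfg, B)
  } else {
    # conv backbones: per-image forward, then stack
    feats <- lapply(idx, function(p) {
      lapply(data$images[[p]], function(im) {
        conv_forward_one(tape, sub_nodes(pn, "conv"), im, model$conv_cfg)
      })
    })
    if (model$kind == "cnn_lr") {
      per_plot <- lapply(feats, function(fl) ad_cbind(tape, fl))
      flat <- ad_rbind(tape, per_plot)
      lr <- sub_nodes(pn, "lr")
      img <- ad_dense(tape, flat, lr$W, lr$b)
      penalty <- ad_sum_sq(tape, lr$W)
    } else {
      xs <- lapply(seq_len(T_len), function(t) {
        ad_rbind(tape, lapply(feats, `[[`, t))
      })
      img <- bilstm_forward(tape, sub_nodes(pn, "lstm"), xs, model$lstm_cfg, B)
    }
  }
  xparts <- list(img)
  if (model$use_seed) {
    xparts <- c(xparts, list(seed_forward(tape, sub_nodes(pn, "seed"), oh_node, dropout)))
  }
  x <- if (length(xparts) > 1L) ad_cbind(tape, xparts) else xparts[[1L]]
  pred <- head_forward(tape, sub_nodes(pn, "head"), x, dropout)
  list(pred = pred, penalty = penalty)
}

# stack nodes row-wise
ad_rbind <- function(tape, nodes) {
  hs <- vapply(nodes, function(nd) nrow(nd$value), 1L)
  offs <- cumsum(c(0L, hs))
  ad_node(tape, do.call(rbind, lapply(nodes, function(nd) nd$value)), function(g) {
    for (i in seq_along(nodes)) {
      ad_accum(nodes[[i]], g[(offs[i] + 1L):offs[i + 1L], , drop = FALSE])
    }
  })
}

#' Predict yields for a list of plot records
#'
#' @param model a `yf_model` (typically trained).
#' @param records list of plot records.
#' @param data optional pre-computed [prepare_model_data()] output.
#' @param chunk maximum plots per forward pass.
#' @return numeric vector of predicted yields in kg/ha.
#' @export
predict_yield <- function(model, records = NULL, data = NULL, chunk = 32L) {
  if (is.null(data)) data <- prepare_model_data(model, records)
  preds <- numeric(data$n)
  for (start in seq.int(1L, data$n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, data$n)
    tape <- ad_tape(training = FALSE)
    pn <- ad_leaves(tape, model$params)
    fwd <- model_forward_batch(tape, pn, model, data, idx, training = FALSE)
    preds[idx] <- as.numeric(fwd$pred$value)
  }
  preds * model$y_scale + model$y_center
}
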