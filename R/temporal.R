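# Encoder-only temporal transformer.
#
# Maps the per-timestamp fused image features (T x D, acquisition order) to a
# single 128-d representation: dense input projection, sinusoidal positional
# encoding, a stack of pre-norm multi-head attention blocks (same block
# structure as the ViT), mean-pooling over timestamps, and a dense output
# layer. Attention is bidirectional: every timestamp attends to every other.

#' Temporal transformer configuration
#'
#' @param d_model token width D of the input features.
#' @param depth number of attention blocks (default 3).
#' @param heads attention heads per block (default 5); per-head width is
#'   `floor(d_model / heads)` and the concatenated heads are projected back
#'   to `d_model`.
#' @param out_dim width of the output image representation (default 128).
#' @param mlp_hidden MLP hidden width.
#' @param use_pe logical; add the sinusoidal positional encoding (disable to
#'   probe permutation equivariance).
#' @return list of class `temporal_config`.
#' @export
temporal_config <- function(d_model = 128L, depth = 3L, heads = 5L,
                            out_dim = 128L, mlp_hidden = 4L * d_model,
                            use_pe = TRUE) {
  stopifnot(depth >= 1, heads >= 1)
  if (d_model %% 2L != 0L) stop("d_model must be even (sine/cosine pairs)")
  structure(list(d_model = as.integer(d_model), depth = as.integer(depth),
                 heads = as.integer(heads), out_dim = as.integer(out_dim),
                 mlp_hidden = as.integer(mlp_hidden),
                 d_k = as.integer(d_model %/% heads), use_pe = isTRUE(use_pe)),
            class = "temporal_config")
}

#' Sinusoidal positional encoding
#'
#' `PE[t, 2i] = sin(t / 10000^(2i/D))`, `PE[t, 2i+1] = cos(t / 10000^(2i/D))`
#' with `t = 0, ..., T-1` and `i = 0, ..., D/2 - 1` (returned 1-based as rows
#' `t+1` and column pairs `(2i+1, 2i+2)`).
#'
#' @param T_len number of timestamps.
#' @param D even encoding width.
#' @return numeric matrix `T_len x D`, entries in `[-1, 1]`.
#' @export
sinusoidal_positional_encoding <- function(T_len, D) {
  if (D %% 2L != 0L) stop("positional encoding width D must be even")
  t <- seq_len(T_len) - 1
  i <- seq_len(D %/% 2L) - 1
  freq <- 1 / 10000^(2 * i / D)
  ang <- outer(t, freq)
  pe <- matrix(0, T_len, D)
  pe[, seq(1L, D, by = 2L)] <- sin(ang)
  pe[, seq(2L, D, by = 2L)] <- cos(ang)
  pe
}

#' Initialise temporal-transformer weights
#'
#' @param config a [temporal_config()]. Draws from the current RNG stream.
#' @return named list of parameter matrices.
#' @export
temporal_init <- function(config) {
  D <- config$d_model
  p <- list(in_W = init_dense(D, D), in_b = init_bias(D))
  for (l in seq_len(config$depth)) {
    p <- c(p, init_block(D, config$heads, config$d_k, config$mlp_hidden, l))
  }
  p$out_W <- init_dense(D, config$out_dim)
  p$out_b <- init_bias(config$out_dim)
  p
}

# tape forward over n_groups sequences of length T (rows sequence-major):
# ((n_groups * T) x D) -> (n_groups x out_dim)
temporal_forward <- function(tape, pn, x_node, n_groups, T_len, config) {
  h <- ad_dense(tape, x_node, pn$in_W, pn$in_b)
  if (config$use_pe) {
    pe <- sinusoidal_positional_encoding(T_len, config$d_model)
    h <- ad_addconst(tape, h, pe[rep(seq_len(T_len), times = n_groups), , drop = FALSE])
  }
  for (l in seq_len(config$depth)) {
    h <- block_forward(tape, pn, h, l, config$heads, config$d_k, n_groups,
                       config$d_model)
  }
  pooled <- ad_group_mean(tape, h, n_groups)
  ad_dense(tape, pooled, pn$out_W, pn$out_b)
}

#' Encode a feature time series to a single representation
#'
#' @param x numeric matrix `T x d_model`, rows ordered by acquisition date
#'   (`T >= 1`).
#' @param params parameters from [temporal_init()].
#' @param config the [temporal_config()].
#' @return numeric vector of length `out_dim`; deterministic given weights.
#' @export
encode_sequence <- function(x, params, config) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (nrow(x) < 1L) stop("time series must have at least one timestamp")
  if (ncol(x) != config$d_model) stop("feature width must equal d_model")
  tape <- ad_tape(training = FALSE)
  pn <- ad_leaves(tape, params)
  xn <- ad_leaf(tape, x)
  as.numeric(temporal_forward(tape, pn, xn, 1L, nrow(x), config)$value)
}
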