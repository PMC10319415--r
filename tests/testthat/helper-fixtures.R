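# Shared fixtures: tiny configurations and random inputs used across files.

tiny_vit_cfg <- function(size = 32L, D = 8L, depth = 1L, heads = 2L) {
  vit_config(image_size = size, patch_size = 16L, embed_dim = D,
             depth = depth, heads = heads, mlp_hidden = 2L * D)
}

tiny_temporal_cfg <- function(D = 8L, depth = 1L, heads = 2L, out = 6L) {
  temporal_config(d_model = D, depth = depth, heads = heads, out_dim = out,
                  mlp_hidden = 2L * D)
}

rand_image <- function(size = 32L, seed = 1L) {
  set.seed(seed)
  array(runif(size * size * 3), dim = c(size, size, 3))
}

# set every parameter matrix in a list to zero
zero_params <- function(p) lapply(p, function(m) m * 0)

# deterministic tiny synthetic dataset shared by the heavier tests
tiny_dataset <- function(n_plots, image_size = 64L, dir_tag = "ds",
                         rng_seed = 7L, yield_params = NULL) {
  out <- file.path(tempdir(), paste0("yf_", dir_tag, "_", n_plots, "_", rng_seed))
  scn <- scene_params(image_size = image_size)
  yp <- if (is.null(yield_params)) yield_model_params() else yield_params
  generate_dataset(n_plots, out, scene = scn, yield_params = yp,
                   rng_seed = rng_seed)
}

# numeric finite-difference gradient of f (scalar) wrt params[[nm]][k]
num_grad <- function(f, params, nm, k, eps = 1e-6) {
  p1 <- params; p1[[nm]][k] <- p1[[nm]][k] + eps
  p0 <- params; p0[[nm]][k] <- p0[[nm]][k] - eps
  (f(p1) - f(p0)) / (2 * eps)
}
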