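# Synthetic plot-image generator.
#
# Stands in for a private field dataset: plots of row-planted soybean imaged
# three times across the season. Each scene is green plant rows over textured
# brown soil, with far rows fore-shortened (the camera looks across the plot
# at a diagonal), canopy coverage growing along a per-plot logistic curve, and
# plot yield generated from final coverage, canopy greenness and an additive
# seed-combination effect. The generator emits ground-truth plant masks and a
# manifest, so segmentation and the full model pipeline can be scored against
# a known truth.

# deterministic per-item seed derived from one base seed (kept < 2^31)
item_seed <- function(base, a, b = 0L) {
  (abs(base) * 100003 + a * 1009 + b * 7) %% 2147483629
}

# run `expr` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Enumerate seed combinations from per-treatment counts
#'
#' Builds the canonical table of seed combinations (treatment x variety x
#' seeding rate). Each treatment contributes a stated number of
#' (variety, rate) combinations; the default counts `c(5, 9, 2, 9, 10, 16)`
#' over six treatment groups give the 51-combination layout of the motivating
#' field trial. Pairs are enumerated in lexicographic (variety, rate) order,
#' extending the seeding-rate pool (110K, 140K, 170K, ...) as far as a
#' treatment's count requires.
#'
#' @param counts_per_treatment non-negative integer vector, one entry per
#'   treatment group.
#' @param treatments character vector of treatment names (recycled defaults).
#' @return data.frame with columns `treatment`, `variety`, `rate`,
#'   `combo_index` (0-based, unique, in enumeration order).
#' @export
enumerate_seed_combos <- function(counts_per_treatment = c(5L, 9L, 2L, 9L, 10L, 16L),
                                  treatments = NULL) {
  if (length(counts_per_treatment) == 0) {
    return(data.frame(treatment = character(), variety = character(),
                      rate = character(), combo_index = integer()))
  }
  if (any(counts_per_treatment < 0)) stop("counts_per_treatment must be non-negative")
  default_names <- c("Non-treated control", "Base seed treatment control",
                     "ILEVO alone", "ILEVO + Base", "Saltro + Base", "Other")
  if (is.null(treatments)) {
    treatments <- if (length(counts_per_treatment) <= length(default_names)) {
      default_names[seq_along(counts_per_treatment)]
    } else {
      paste0("Treatment ", seq_along(counts_per_treatment))
    }
  }
  varieties <- c("resistant", "susceptible")
  rows <- lapply(seq_along(counts_per_treatment), function(i) {
    k <- counts_per_treatment[i]
    if (k == 0) return(NULL)
    n_rates <- ceiling(k / length(varieties))
    rates <- paste0(110 + 30 * (seq_len(n_rates) - 1), "K")
    grid <- expand.grid(rate = rates, variety = varieties,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    # lexicographic (variety, rate)
    grid <- grid[order(grid$variety, grid$rate), c("variety", "rate")]
    grid <- grid[seq_len(k), , drop = FALSE]
    data.frame(treatment = treatments[i], grid, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$combo_index <- seq_len(nrow(out)) - 1L
  out
}

#' Scene parameters for the synthetic renderer
#'
#' @param image_size image side in pixels (square images).
#' @param n_timestamps number of acquisition dates per plot.
#' @param n_rows number of crop rows.
#' @param perspective_factor in `[0, 1]`; fractional shrink of the far-end
#'   (top) row band relative to the near end, emulating the diagonal camera.
#' @param soil_color_mean,plant_color_mean RGB triples in `[0, 1]`.
#' @param coverage_curve list with `c_max`, `rate`, `midpoint`: canopy
#'   coverage at timestamp t is `c_max * plogis(rate * (t - midpoint))`.
#' @param row_fill fraction of each row band that the canopy can occupy at
#'   full coverage (the rest stays inter-row soil).
#' @param noise_sd per-pixel Gaussian texture noise, in [0,1] intensity units.
#' @return list of class `scene_params`.
#' @export
scene_params <- function(image_size = 128L, n_timestamps = 3L, n_rows = 6L,
                         perspective_factor = 0.4,
                         soil_color_mean = c(0.47, 0.35, 0.24),
                         plant_color_mean = c(0.24, 0.47, 0.20),
                         coverage_curve = list(c_max = 0.85, rate = 1.8, midpoint = 0.7),
                         row_fill = 0.7, noise_sd = 0.04) {
  if (image_size < 1) stop("image_size must be positive")
  stopifnot(n_timestamps >= 1, n_rows >= 1,
            perspective_factor >= 0, perspective_factor <= 1,
            all(soil_color_mean >= 0 & soil_color_mean <= 1),
            all(plant_color_mean >= 0 & plant_color_mean <= 1))
  structure(list(image_size = as.integer(image_size),
                 n_timestamps = as.integer(n_timestamps),
                 n_rows = as.integer(n_rows),
                 perspective_factor = perspective_factor,
                 soil_color_mean = soil_color_mean,
                 plant_color_mean = plant_color_mean,
                 coverage_curve = coverage_curve,
                 row_fill = row_fill,
                 noise_sd = noise_sd),
            class = "scene_params")
}

#' Canopy coverage at a timestamp under a logistic growth curve
#' @param curve list with `c_max`, `rate`, `midpoint`.
#' @param timestamp 0-based timestamp index.
#' @return coverage fraction in `[0, 1]`.
#' @export
coverage_at <- function(curve, timestamp) {
  cv <- curve$c_max * stats::plogis(curve$rate * (timestamp - curve$midpoint))
  min(max(cv, 0), 1)
}

#' Render one synthetic plot image with its ground-truth plant mask
#'
#' Paints `n_rows` horizontal plant bands over noisy soil. Row bands shrink
#' towards the top of the image by `perspective_factor` (far rows look
#' thinner). Within each band the canopy occupies a centred strip whose
#' thickness is proportional to coverage at the requested timestamp.
#'
#' @param scene a [scene_params()] object.
#' @param timestamp 0-based timestamp (`< n_timestamps`).
#' @param rng_seed integer; the image is a pure function of
#'   `(scene, timestamp, rng_seed)`.
#' @param coverage optional override of the coverage fraction in `[0, 1]`.
#' @param greenness in `[0, 1]`; scales the green channel of the canopy.
#' @return list with `image` (H x W x 3 array) and `mask` (logical H x W).
#' @export
render_plot_image <- function(scene, timestamp, rng_seed, coverage = NULL,
                              greenness = 0.5) {
  if (timestamp < 0 || timestamp >= scene$n_timestamps) {
    stop("timestamp must be in [0, n_timestamps)")
  }
  if (scene$image_size < 1) stop("image_size must be positive")
  if (is.null(coverage)) coverage <- coverage_at(scene$coverage_curve, timestamp)
  stopifnot(coverage >= 0, coverage <= 1)
  sz <- scene$image_size
  with_seed(rng_seed, {
    img <- array(stats::rnorm(sz * sz * 3, 0, scene$noise_sd), dim = c(sz, sz, 3))
    for (ch in 1:3) img[, , ch] <- img[, , ch] + scene$soil_color_mean[ch]
    mask <- matrix(FALSE, sz, sz)
    # row-band heights: top (far) rows shrunk by perspective_factor
    n_rows <- scene$n_rows
    wts <- if (n_rows == 1) 1 else {
      (1 - scene$perspective_factor) +
        scene$perspective_factor * (seq_len(n_rows) - 1) / (n_rows - 1)
    }
    bounds <- round(c(0, cumsum(wts / sum(wts))) * sz)
    plant_col <- scene$plant_color_mean * c(1, 0.7 + 0.6 * greenness, 1)
    plant_col <- pmin(plant_col, 1)
    for (r in seq_len(n_rows)) {
      top <- bounds[r] + 1L
      bot <- bounds[r + 1L]
      if (bot < top) next
      band_h <- bot - top + 1L
      strip_h <- round(coverage * scene$row_fill * band_h)
      if (strip_h < 1) next
      mid <- (top + bot) / 2
      r0 <- max(top, floor(mid - strip_h / 2) + 1L)
      r1 <- min(bot, r0 + strip_h - 1L)
      rows <- r0:r1
      for (ch in 1:3) {
        img[rows, , ch] <- plant_col[ch] +
          matrix(stats::rnorm(length(rows) * sz, 0, scene$noise_sd), length(rows), sz)
      }
      mask[rows, ] <- TRUE
    }
    img[img < 0] <- 0
    img[img > 1] <- 1
    list(image = img, mask = mask)
  })
}

#' Yield-model parameters for the synthetic generator
#'
#' Yield (kg/ha) is linear in final canopy coverage and greenness plus an
#' additive per-combination seed effect and Gaussian noise. By default a
#' fraction of combinations ("bad combos") carries a large negative effect,
#' which produces the left-skewed yield distribution with its bulk between
#' 3500 and 5000 kg/ha and makes the seed branch of the model matter most for
#' low-yield plots.
#'
#' @param n_combos number of seed combinations.
#' @param base_yield intercept, kg/ha.
#' @param beta_coverage kg/ha per unit final coverage.
#' @param beta_greenness kg/ha per unit greenness.
#' @param noise_sd residual sd, kg/ha.
#' @param frac_bad fraction of combos with a large negative effect.
#' @param bad_effect_range kg/ha range (negative) for bad-combo effects.
#' @param good_sd sd of the small centred effects of the remaining combos.
#' @param effect_seed integer seed fixing which combos are bad and their sizes.
#' @param seed_effects optional explicit effect vector (overrides the draw).
#' @return list of class `yield_model_params` with `seed_effects` (length
#'   `n_combos`, kg/ha) and `bad_combos` (0-based indices).
#' @export
yield_model_params <- function(n_combos = 51L, base_yield = 3450,
                               beta_coverage = 1400, beta_greenness = 300,
                               noise_sd = 110, frac_bad = 0.2,
                               bad_effect_range = c(-950, -650), good_sd = 60,
                               effect_seed = 20L, seed_effects = NULL) {
  if (is.null(seed_effects)) {
    n_bad <- round(frac_bad * n_combos)
    drawn <- with_seed(effect_seed, {
      bad <- sort(sample.int(n_combos, n_bad))
      eff <- stats::rnorm(n_combos, 0, good_sd)
      eff[bad] <- stats::runif(n_bad, bad_effect_range[1], bad_effect_range[2])
      list(eff = eff, bad = bad)
    })
    seed_effects <- drawn$eff
    bad_combos <- drawn$bad - 1L
  } else {
    stopifnot(length(seed_effects) == n_combos)
    bad_combos <- which(seed_effects <= -250) - 1L
  }
  structure(list(n_combos = as.integer(n_combos), base_yield = base_yield,
                 beta_coverage = beta_coverage, beta_greenness = beta_greenness,
                 noise_sd = noise_sd, seed_effects = seed_effects,
                 bad_combos = bad_combos),
            class = "yield_model_params")
}

#' Sample one plot yield from the synthetic yield model
#'
#' @param coverage_final final-timestamp canopy coverage in `[0, 1]`.
#' @param greenness canopy greenness in `[0, 1]`.
#' @param combo_index 0-based seed-combination index.
#' @param params a [yield_model_params()] object.
#' @param rng_seed integer seed for the noise draw.
#' @return yield in kg/ha.
#' @export
sample_yield <- function(coverage_final, greenness, combo_index, params, rng_seed) {
  stopifnot(coverage_final >= 0, coverage_final <= 1,
            greenness >= 0, greenness <= 1,
            combo_index >= 0, combo_index < params$n_combos)
  mu <- params$base_yield +
    params$beta_coverage * coverage_final +
    params$beta_greenness * greenness +
    params$seed_effects[combo_index + 1L]
  if (params$noise_sd > 0) {
    mu + with_seed(rng_seed, stats::rnorm(1, 0, params$noise_sd))
  } else {
    mu
  }
}

# draw one plot's latent growth/appearance state
draw_plot_state <- function(seed) {
  with_seed(seed, list(
    c_max = stats::runif(1, 0.7, 1.0),
    rate = stats::runif(1, 1.2, 2.5),
    midpoint = stats::runif(1, 0.2, 1.2),
    greenness = stats::runif(1, 0.3, 0.7)
  ))
}

#' Generate a labelled synthetic dataset on disk
#'
#' Renders `n_plots` plot time series (images as PPM, ground-truth masks as
#' PGM), assigns seed combinations near-uniformly across the enumeration
#' (counts differ by at most one), samples yields from the yield model, and
#' writes a manifest CSV. All randomness flows from `rng_seed` through
#' per-plot/timestamp derived seeds, so any item is reproducible in isolation.
#'
#' @param n_plots number of plots (>= 1).
#' @param out_dir output directory (created if needed).
#' @param scene a [scene_params()] object.
#' @param yield_params a [yield_model_params()] object.
#' @param combos combo table from [enumerate_seed_combos()].
#' @param rng_seed master integer seed.
#' @return list of class `syn_dataset`: `manifest` (data.frame), `truth`
#'   (the yield model), `scene`, `combos`, `dir`.
#' @export
generate_dataset <- function(n_plots, out_dir,
                             scene = scene_params(),
                             yield_params = yield_model_params(),
                             combos = enumerate_seed_combos(),
                             rng_seed = 1L) {
  stopifnot(n_plots >= 1)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  n_combos <- nrow(combos)
  stopifnot(yield_params$n_combos == n_combos)
  # balanced assignment: counts per combo in {floor, ceil}(n_plots / n_combos)
  assignment <- with_seed(item_seed(rng_seed, 0L), {
    sample(rep_len(seq_len(n_combos) - 1L, n_plots))
  })
  rows <- vector("list", n_plots * scene$n_timestamps)
  k <- 0L
  for (p in seq_len(n_plots)) {
    st <- draw_plot_state(item_seed(rng_seed, p, 1L))
    curve <- list(c_max = st$c_max, rate = st$rate, midpoint = st$midpoint)
    combo_idx <- assignment[p]
    cov_final <- coverage_at(curve, scene$n_timestamps - 1L)
    y <- sample_yield(cov_final, st$greenness, combo_idx, yield_params,
                      item_seed(rng_seed, p, 2L))
    plot_scene <- scene
    plot_scene$coverage_curve <- curve
    for (t in seq_len(scene$n_timestamps) - 1L) {
      rend <- render_plot_image(plot_scene, t, item_seed(rng_seed, p, 10L + t),
                                greenness = st$greenness)
      img_path <- file.path(out_dir, sprintf("plot%04d_t%d.ppm", p, t))
      mask_path <- file.path(out_dir, sprintf("plot%04d_t%d_mask.pgm", p, t))
      write_ppm(rend$image, img_path)
      write_pgm(rend$mask, mask_path)
      k <- k + 1L
      rows[[k]] <- data.frame(
        plot_id = p, timestamp = t,
        image_path = img_path, mask_path = mask_path,
        treatment = combos$treatment[combo_idx + 1L],
        variety = combos$variety[combo_idx + 1L],
        rate = combos$rate[combo_idx + 1L],
        combo_index = combo_idx,
        yield_kg_ha = y,
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  structure(list(manifest = manifest, truth = yield_params, scene = scene,
                 combos = combos, dir = out_dir),
            class = "syn_dataset")
}
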