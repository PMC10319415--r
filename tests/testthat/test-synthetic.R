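# Synthetic data generator: combination enumeration, scene rendering, the
# yield model, and dataset-level invariants.

test_that("seed-combination enumeration matches the per-treatment counts", {
  combos <- enumerate_seed_combos(c(5, 9, 2, 9, 10, 16))
  expect_equal(nrow(combos), 51L)
  expect_equal(combos$combo_index, 0:50)
  expect_equal(as.numeric(table(factor(combos$treatment,
                                       levels = unique(combos$treatment)))),
               c(5, 9, 2, 9, 10, 16))
  # unique triples, deterministic re-enumeration
  expect_false(anyDuplicated(combos[c("treatment", "variety", "rate")]) > 0)
  expect_identical(combos, enumerate_seed_combos(c(5, 9, 2, 9, 10, 16)))

  expect_equal(nrow(enumerate_seed_combos(integer(0))), 0L)
  two <- enumerate_seed_combos(c(1, 1))
  expect_equal(two$combo_index, c(0L, 1L))
  expect_error(enumerate_seed_combos(c(2, -1)), "non-negative")
})

test_that("rendered scenes honour coverage and are seed-deterministic", {
  scn <- scene_params(image_size = 48L, n_rows = 4L)
  r0 <- render_plot_image(scn, 0L, rng_seed = 5L, coverage = 0)
  expect_false(any(r0$mask))

  r1 <- render_plot_image(scn, 2L, rng_seed = 5L, coverage = 1)
  # at full coverage the mask fills >= 90% of the row-band area
  expect_gte(sum(r1$mask) / (scn$row_fill * 48 * 48), 0.9)

  ra <- render_plot_image(scn, 1L, rng_seed = 9L)
  rb <- render_plot_image(scn, 1L, rng_seed = 9L)
  expect_identical(ra$image, rb$image)
  expect_identical(ra$mask, rb$mask)
  rc <- render_plot_image(scn, 1L, rng_seed = 10L)
  expect_false(identical(ra$image, rc$image))

  expect_error(render_plot_image(scn, 3L, 1L), "timestamp")
  expect_error(scene_params(image_size = 0L), "positive")
})

test_that("mask pixels are greener than soil pixels for the default palette", {
  scn <- scene_params(image_size = 48L)
  for (seed in c(2L, 3L, 4L)) {
    r <- render_plot_image(scn, 2L, rng_seed = seed)
    exg <- excess_green(r$image)
    expect_gt(min(exg[r$mask]), mean(exg[!r$mask]))
  }
})

test_that("rendered coverage is non-decreasing across timestamps", {
  for (seed in 1:5) {
    st <- yieldformer:::draw_plot_state(seed)
    scn <- scene_params(image_size = 48L,
                        coverage_curve = list(c_max = st$c_max, rate = st$rate,
                                              midpoint = st$midpoint))
    fracs <- vapply(0:2, function(t) {
      mean(render_plot_image(scn, t, rng_seed = seed)$mask)
    }, 1)
    expect_true(all(diff(fracs) >= 0))
  }
})

test_that("sample_yield reproduces the linear form and its Monte-Carlo mean", {
  yp <- yield_model_params(n_combos = 5L, base_yield = 4000,
                           beta_coverage = 0, beta_greenness = 0, noise_sd = 0,
                           seed_effects = rep(0, 5))
  expect_identical(sample_yield(0.5, 0.5, 2L, yp, 1L), 4000)

  yp2 <- yield_model_params(n_combos = 5L, base_yield = 4000,
                            beta_coverage = 1200, beta_greenness = 250,
                            noise_sd = 0, seed_effects = c(0, -300, 50, 0, 0))
  expect_equal(sample_yield(0.6, 0.4, 1L, yp2, 1L),
               4000 + 1200 * 0.6 + 250 * 0.4 - 300)

  yp3 <- yield_model_params(n_combos = 5L, base_yield = 4000,
                            beta_coverage = 1200, beta_greenness = 250,
                            noise_sd = 150, seed_effects = c(0, -300, 50, 0, 0))
  n <- 4000L
  draws <- vapply(seq_len(n), function(i) sample_yield(0.6, 0.4, 1L, yp3, i), 1)
  noiseless <- 4000 + 1200 * 0.6 + 250 * 0.4 - 300
  expect_lt(abs(mean(draws) - noiseless), 3 * 150 / sqrt(n))
  # deterministic given seed
  expect_identical(sample_yield(0.6, 0.4, 1L, yp3, 77L),
                   sample_yield(0.6, 0.4, 1L, yp3, 77L))
})

test_that("generated datasets have complete manifests and balanced combos", {
  ds <- tiny_dataset(12, image_size = 32L, dir_tag = "man")
  expect_equal(nrow(ds$manifest), 12L * 3L)
  expect_true(all(table(ds$manifest$plot_id) == 3L))
  expect_true(all(file.exists(ds$manifest$image_path)))
  expect_true(all(file.exists(ds$manifest$mask_path)))

  # balanced combo assignment over 450 plots: every combo count in {8, 9}
  scn <- scene_params(image_size = 16L, n_rows = 3L)
  big <- generate_dataset(450, file.path(tempdir(), "yf_bal"), scene = scn,
                          rng_seed = 3L)
  counts <- table(big$manifest$combo_index[big$manifest$timestamp == 0])
  expect_equal(length(counts), 51L)
  expect_true(all(counts %in% c(8L, 9L)))

  # fixed seed reproduces the manifest exactly
  ds2 <- tiny_dataset(12, image_size = 32L, dir_tag = "man2")
  m1 <- ds$manifest; m2 <- ds2$manifest
  m1$image_path <- m2$image_path <- m1$mask_path <- m2$mask_path <- NULL
  expect_identical(m1, m2)
})

test_that("the default yield model is left-skewed with its bulk in 3500-5000 kg/ha", {
  yp <- yield_model_params()
  ys <- vapply(seq_len(10000L), function(i) {
    st <- yieldformer:::draw_plot_state(yieldformer:::item_seed(99L, i, 1L))
    cov <- coverage_at(list(c_max = st$c_max, rate = st$rate,
                            midpoint = st$midpoint), 2L)
    sample_yield(cov, st$greenness, (i - 1L) %% 51L, yp,
                 yieldformer:::item_seed(99L, i, 2L))
  }, 1)
  expect_lt(describe_yield(ys)$skewness, 0)
  expect_gt(mean(ys >= 3500 & ys <= 5000), 0.9)
})
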