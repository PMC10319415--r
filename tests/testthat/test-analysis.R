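# Group-average baselines, ridge reference models, counterfactual analysis
# and descriptive statistics.

test_that("average-of-all baseline behaves like the mean predictor", {
  expect_equal(average_all_baseline(rep(7, 5), 3), rep(7, 3))
  expect_error(average_all_baseline(numeric(0), 3), "empty")
  set.seed(1)
  ytr <- rnorm(2000, 4500, 400)
  yte <- rnorm(2000, 4500, 400)
  preds <- average_all_baseline(ytr, length(yte))
  expect_lt(abs(r_squared(yte, preds)), 0.05)
  # never beats the per-set-mean oracle
  expect_gte(rmse(yte, preds), rmse(yte, rep(mean(yte), length(yte))))
})

test_that("per-combo averages reduce to and improve on the global mean as appropriate", {
  # single combo: identical to average_all
  ytr <- c(4, 5, 6)
  expect_equal(aver_seed_baseline(ytr, rep(0L, 3), rep(0L, 4)),
               average_all_baseline(ytr, 4))
  # strong seed effects, no image signal: beats the global mean
  set.seed(2)
  eff <- c(0, -800, 400, 100, -300)
  ctr <- sample(0:4, 300, replace = TRUE)
  cte <- sample(0:4, 100, replace = TRUE)
  ytr <- 4500 + eff[ctr + 1] + rnorm(300, 0, 60)
  yte <- 4500 + eff[cte + 1] + rnorm(100, 0, 60)
  expect_lt(rmse(yte, aver_seed_baseline(ytr, ctr, cte)),
            rmse(yte, average_all_baseline(ytr, length(yte))))
  # unseen combo falls back to the global mean, with a message
  expect_message(p <- aver_seed_baseline(c(1, 2), c(0L, 0L), c(0L, 3L)), "unseen")
  expect_equal(p[2], 1.5)
})

test_that("ridge reference models use the stated feature widths and orderings", {
  # image-driven world: yields depend on coverage only, seed effects are zero
  yp <- yield_model_params(frac_bad = 0, good_sd = 0, noise_sd = 60)
  ds <- tiny_dataset(60, image_size = 32L, dir_tag = "lr", yield_params = yp)
  recs <- load_records(ds, image_size = 32L)
  combo <- vapply(recs, `[[`, 1L, "combo_index")
  sp <- split_dataset(combo, c(44, 4, 12), rng_seed = 3L)
  sp2 <- list(train = c(sp$train, sp$val), test = sp$test)
  r1 <- lr_reference_model(recs, 1, sp2)
  r2 <- lr_reference_model(recs, 2, sp2, downsample = 16L)
  r3 <- lr_reference_model(recs, 3, sp2, downsample = 16L)
  expect_equal(attr(r1, "n_features"), 51L)
  expect_equal(attr(r2, "n_features"), 51L + 256L)
  # variant 3 adds (T-1) more image blocks of the same width
  expect_equal(attr(r3, "n_features"), attr(r2, "n_features") + 2L * 256L)
  # image-driven yields: adding the latest image beats seed-only
  expect_lt(r2$rmse, r1$rmse)
  expect_error(lr_reference_model(recs, 4, sp2), "variant")
})

test_that("seed-only ridge regression on pure-noise yields has no skill", {
  set.seed(4)
  r2s <- vapply(1:20, function(s) {
    recs <- lapply(1:60, function(i) {
      list(images = list(), combo_index = (i - 1L) %% 10L, yield = rnorm(1, 4500, 300))
    })
    sp <- list(train = 1:45, test = 46:60)
    lr_reference_model(recs, 1, sp, n_combos = 10L)$r_squared
  }, 1)
  expect_lt(mean(r2s), 0.05)
})

test_that("IQR status rule matches brute-force enumeration on crafted boxes", {
  preds <- 1:51
  q <- quantile(preds, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  for (tp in c(-100, q[1] - 1.5 * iqr - 0.01, q[1] - 0.01, q[1], 26, q[2],
               q[2] + 0.01, 1000)) {
    expected <- if (tp < q[1] - 1.5 * iqr) "low_outlier"
      else if (tp >= q[1] && tp <= q[2]) "inside_iqr"
      else "outside_iqr"
    expect_identical(iqr_status(tp, q[1], q[2]), expected)
  }
})

test_that("iqr_coverage arithmetic matches the published worked example", {
  # 47 of 68 inside is 69.1% to one decimal
  res <- data.frame(status = c(rep("inside_iqr", 47), rep("outside_iqr", 17),
                               rep("low_outlier", 4)))
  cov <- iqr_coverage(res)
  expect_equal(round(100 * cov$fraction_inside, 1), 69.1)
  expect_equal(cov$fraction_inside + cov$fraction_outside, 1)
  expect_equal(cov$n_low_outliers, 4L)
  all_in <- data.frame(status = rep("inside_iqr", 10))
  expect_equal(iqr_coverage(all_in),
               list(fraction_inside = 1, fraction_outside = 0, n_low_outliers = 0L))
  expect_error(iqr_coverage(res[0, , drop = FALSE]), "empty")
})

test_that("a zero-weight seed branch collapses the counterfactual box", {
  ds <- tiny_dataset(3, image_size = 64L, dir_tag = "cf0")
  recs <- load_records(ds, image_size = 64L)
  model <- build_model("proposed", preset = "small", n_combos = 51L, rng_seed = 5L)
  for (nm in grep("^seed\\.", names(model$params), value = TRUE)) {
    model$params[[nm]] <- model$params[[nm]] * 0
  }
  model$trained <- TRUE
  res <- counterfactual_seed_analysis(model, recs)
  expect_equal(res$iqr, rep(0, 3))
  expect_true(all(res$status == "inside_iqr"))
  preds <- attr(res, "predictions")
  expect_equal(apply(preds, 1, function(r) diff(range(r))), rep(0, 3))
})

test_that("the true-combo counterfactual equals the ordinary forward pass bit-exactly", {
  ds <- tiny_dataset(4, image_size = 64L, dir_tag = "cfb")
  recs <- load_records(ds, image_size = 64L)
  model <- build_model("proposed", preset = "small", n_combos = 51L, rng_seed = 6L)
  model$trained <- TRUE
  res <- counterfactual_seed_analysis(model, recs)
  for (i in seq_along(recs)) {
    expect_identical(res$true_prediction[i], forward_proposed(recs[[i]], model))
  }
  expect_error(counterfactual_seed_analysis(
    build_model("proposed", preset = "small", rng_seed = 6L), recs), "trained")
})

test_that("describe_yield matches closed forms and the normal reference", {
  d <- describe_yield(c(-1, 1, -1, 1))
  expect_equal(d$skewness, 0)
  expect_equal(d$kurtosis, 1)
  set.seed(7)
  dn <- describe_yield(rnorm(1e5))
  expect_equal(dn$kurtosis, 3, tolerance = 0.1 / 3)
  expect_lt(abs(dn$skewness), 0.05)
  expect_error(describe_yield(c(1, 2, 3)), "four")
  expect_error(describe_yield(rep(2, 10)), "zero variance")
})
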