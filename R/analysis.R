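# Reference comparisons and seed-influence analyses: group-average baselines,
# ridge-regression reference models on flattened pixel features, descriptive
# yield statistics, and the counterfactual seed-combination experiment (every
# test plot predicted under all combinations, true prediction located against
# the quartile box of the 51 predictions).

#' Mean-of-training-set baseline predictions
#'
#' Every test plot is predicted as the mean training yield. Against the test
#' set's own mean, this baseline has R-squared near zero (exactly zero when
#' train and test means coincide).
#'
#' @param train_yields numeric vector of training yields (non-empty).
#' @param n_test number of test predictions to emit.
#' @return numeric vector of length `n_test`.
#' @export
average_all_baseline <- function(train_yields, n_test) {
  if (length(train_yields) < 1L) stop("empty training set")
  rep(mean(train_yields), n_test)
}

#' Per-seed-combination group-mean baseline predictions
#'
#' Each test plot is predicted as the mean training yield of its seed
#' combination; combinations unseen in training fall back to the global
#' training mean (reported via a message).
#'
#' @param train_yields,train_combos training yields and 0-based combo indices.
#' @param test_combos combo indices of the test plots.
#' @return numeric vector of predictions, one per test plot.
#' @export
aver_seed_baseline <- function(train_yields, train_combos, test_combos) {
  if (length(train_yields) < 1L) stop("empty training set")
  mu_all <- mean(train_yields)
  mu_g <- tapply(train_yields, train_combos, mean)
  key <- as.character(test_combos)
  preds <- as.numeric(mu_g[key])
  miss <- is.na(preds)
  if (any(miss)) {
    message(sum(miss), " test plots carry combos unseen in training; ",
            "using the global training mean")
    preds[miss] <- mu_all
  }
  preds
}

# channel-mean image flattened to a feature vector, optionally down-sampled
image_lr_features <- function(img, downsample = NULL) {
  if (!is.null(downsample)) img <- resize_bilinear(img, downsample, downsample)
  as.numeric((img[, , 1] + img[, , 2] + img[, , 3]) / 3)
}

#' Ridge-regression reference models on flat features
#'
#' Three linear models of increasing input: variant 1 uses the one-hot seed
#' combination only; variant 2 adds the channel-averaged, flattened latest
#' image; variant 3 adds all timestamps' images. Fit by ridge regression
#' (glmnet, alpha = 0) on the train split, evaluated on the test split.
#'
#' @param records list of plot records (`images`, `combo_index`, `yield`).
#' @param variant 1, 2 or 3.
#' @param split list with `train` and `test` index vectors.
#' @param n_combos one-hot width.
#' @param lambda ridge penalty.
#' @param downsample optional image side to down-sample to before flattening.
#' @return a [metric_report()] on the test split, with the fitted feature
#'   width in attribute `"n_features"`.
#' @export
lr_reference_model <- function(records, variant, split, n_combos = 51L,
                               lambda = 1, downsample = NULL) {
  if (!variant %in% 1:3) stop("unknown variant: ", variant)
  feats <- function(r) {
    x <- as.numeric(one_hot(r$combo_index, n_combos))
    T_len <- length(r$images)
    if (variant >= 2) {
      x <- c(x, image_lr_features(r$images[[T_len]], downsample))
    }
    if (variant == 3 && T_len > 1) {
      for (t in seq_len(T_len - 1L)) {
        x <- c(x, image_lr_features(r$images[[t]], downsample))
      }
    }
    x
  }
  X <- do.call(rbind, lapply(records, feats))
  y <- vapply(records, `[[`, 1, "yield")
  fit <- glmnet::glmnet(X[split$train, , drop = FALSE], y[split$train],
                        alpha = 0, lambda = lambda, standardize = TRUE)
  yhat <- as.numeric(stats::predict(fit, X[split$test, , drop = FALSE], s = lambda))
  rep <- metric_report(y[split$test], yhat)
  attr(rep, "n_features") <- ncol(X)
  rep
}

#' Counterfactual seed-combination analysis
#'
#' For each plot, predicts yield with its images fixed and the seed
#' combination substituted by every enumerated combination (n_combos
#' predictions, one of them the true combination). The true prediction is
#' located against the quartile box (linear-interpolation percentiles) of the
#' counterfactual distribution. The image branch is computed once per plot,
#' so the true-combo counterfactual equals [forward_proposed()] bit-exactly.
#'
#' @param model a trained proposed-kind `yf_model`.
#' @param records list of plot records.
#' @return data.frame (one row per plot): `plot_id`, `true_combo_index`,
#'   `q1`, `median`, `q3`, `iqr`, `true_prediction`, `status` in
#'   `{"inside_iqr", "outside_iqr", "low_outlier"}`; the full n x n_combos
#'   prediction matrix is in attribute `"predictions"`.
#' @export
counterfactual_seed_analysis <- function(model, records) {
  stopifnot(inherits(model, "yf_model"), model$kind == "proposed")
  if (!isTRUE(model$trained)) stop("model must be trained")
  n <- length(records)
  C <- model$n_combos
  pred_mat <- matrix(0, n, C)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    r <- records[[i]]
    v <- image_branch_proposed(model, r$images)
    preds <- vapply(seq_len(C) - 1L, function(ci) head_from_branch(model, v, ci), 1)
    pred_mat[i, ] <- preds
    qs <- stats::quantile(preds, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- qs[3] - qs[1]
    tp <- preds[r$combo_index + 1L]
    status <- iqr_status(tp, qs[1], qs[3])
    rows[[i]] <- data.frame(plot_id = r$plot_id %||% i,
                            true_combo_index = r$combo_index,
                            q1 = qs[1], median = qs[2], q3 = qs[3], iqr = iqr,
                            true_prediction = tp, status = status,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "predictions") <- pred_mat
  out
}

#' Classify a true prediction against its counterfactual quartile box
#'
#' `low_outlier` when below `Q1 - 1.5 IQR`, `inside_iqr` when within
#' `[Q1, Q3]`, otherwise `outside_iqr`.
#'
#' @param true_prediction scalar prediction under the true combination.
#' @param q1,q3 lower/upper quartiles of the counterfactual predictions.
#' @return status string.
#' @export
iqr_status <- function(true_prediction, q1, q3) {
  iqr <- q3 - q1
  if (true_prediction < q1 - 1.5 * iqr) {
    "low_outlier"
  } else if (true_prediction >= q1 && true_prediction <= q3) {
    "inside_iqr"
  } else {
    "outside_iqr"
  }
}

#' Coverage of true predictions by the counterfactual IQR boxes
#'
#' @param results data.frame from [counterfactual_seed_analysis()] (or any
#'   frame with a `status` column using the same levels).
#' @return list: `fraction_inside`, `fraction_outside` (they sum to one),
#'   `n_low_outliers`.
#' @export
iqr_coverage <- function(results) {
  if (NROW(results) == 0L) stop("empty result list")
  inside <- mean(results$status == "inside_iqr")
  list(fraction_inside = inside,
       fraction_outside = 1 - inside,
       n_low_outliers = sum(results$status == "low_outlier"))
}

#' Moment-based skewness and kurtosis of a yield sample
#'
#' Skewness `m3 / m2^1.5` and Pearson (non-excess) kurtosis `m4 / m2^2`, the
#' convention under which a normal sample scores 3.
#'
#' @param yields numeric vector, `n >= 4`, non-constant.
#' @return list with `skewness` and `kurtosis`.
#' @export
describe_yield <- function(yields) {
  n <- length(yields)
  if (n < 4L) stop("need at least four observations")
  m <- mean(yields)
  d <- yields - m
  m2 <- mean(d^2)
  if (m2 == 0) stop("moments undefined for zero variance")
  list(skewness = mean(d^3) / m2^1.5, kurtosis = mean(d^4) / m2^2)
}
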