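# Training loop, data splitting, and evaluation metrics.

#' Training configuration
#'
#' Published settings: MSE loss, Adam at learning rate 0.001, dropout 0.25,
#' early stopping with patience 10 on validation loss and best-weight
#' restore. Batch size and epoch cap are not published; defaults are 16/200.
#'
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size.
#' @param max_epochs epoch cap.
#' @param patience early-stopping patience in epochs (>= 1).
#' @param rng_seed integer seed driving shuffling and dropout.
#' @return list of class `train_config`.
#' @export
train_config <- function(lr = 0.001, batch_size = 16L, max_epochs = 200L,
                         patience = 10L, rng_seed = 1L) {
  stopifnot(lr > 0, patience >= 1, batch_size >= 1, max_epochs >= 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

#' Split plot indices into train/validation/test sets
#'
#' Reproducible shuffle split with exact requested sizes, approximately
#' stratified by seed combination: plots are ordered round-robin across
#' randomly shuffled combination groups before being cut into the three
#' partitions, so every combination is spread over the sets as far as group
#' sizes allow.
#'
#' @param combo_index 0-based combination index per plot (any grouping
#'   labels; use a constant vector for a plain shuffle split).
#' @param counts integer vector `(train, val, test)`; must sum to the number
#'   of plots.
#' @param rng_seed integer seed.
#' @return list with integer index vectors `train`, `val`, `test` (disjoint,
#'   exhaustive).
#' @export
split_dataset <- function(combo_index, counts, rng_seed = 1L) {
  n <- length(combo_index)
  if (length(counts) != 3L || sum(counts) != n) {
    stop("counts must be length 3 and sum to the number of plots (", n, ")")
  }
  ord <- with_seed(rng_seed, {
    # shuffle within combo, then interleave combos round-robin
    by_combo <- split(seq_len(n), combo_index)
    by_combo <- lapply(by_combo, sample)
    by_combo <- sample(by_combo)
    maxlen <- max(lengths(by_combo))
    out <- integer(0)
    for (k in seq_len(maxlen)) {
      for (g in by_combo) if (length(g) >= k) out <- c(out, g[k])
    }
    out
  })
  list(train = sort(ord[seq_len(counts[1])]),
       val = sort(ord[counts[1] + seq_len(counts[2])]),
       test = sort(ord[counts[1] + counts[2] + seq_len(counts[3])]))
}

#' Train a model with Adam, MSE loss and early stopping
#'
#' Targets are standardised (z-scored on the training split) before the MSE
#' loss; predictions are automatically mapped back to kg/ha. Validation loss
#' is computed without dropout after every epoch; training stops when it has
#' not improved for `patience` epochs and the best-validation weights are
#' restored.
#'
#' @param model a `yf_model`.
#' @param train_records,val_records lists of plot records (non-empty).
#' @param config a [train_config()].
#' @param train_data,val_data optional pre-computed [prepare_model_data()]
#'   outputs (weights-independent, so reusable across runs).
#' @param verbose print per-epoch losses?
#' @return the trained model, with `$history` (data.frame epoch/train_loss/
#'   val_loss, standardised units) and `$trained = TRUE`.
#' @export
train_model <- function(model, train_records = NULL, val_records = NULL,
                        config = train_config(), train_data = NULL,
                        val_data = NULL, verbose = FALSE) {
  if (is.null(train_data)) train_data <- prepare_model_data(model, train_records)
  if (is.null(val_data)) val_data <- prepare_model_data(model, val_records)
  stopifnot(train_data$n >= 1, val_data$n >= 1)
  model$y_center <- mean(train_data$y)
  model$y_scale <- stats::sd(train_data$y)
  if (!is.finite(model$y_scale) || model$y_scale == 0) model$y_scale <- 1
  ytr <- (train_data$y - model$y_center) / model$y_scale
  yva <- (val_data$y - model$y_center) / model$y_scale

  st <- adam_init(model$params, lr = config$lr)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  hist <- vector("list", config$max_epochs)
  n_epochs <- 0L

  val_loss <- function(params) {
    tot <- 0
    for (start in seq.int(1L, val_data$n, by = 64L)) {
      idx <- start:min(start + 63L, val_data$n)
      tape <- ad_tape(training = FALSE)
      pn <- ad_leaves(tape, params)
      fwd <- model_forward_batch(tape, pn, model, val_data, idx, training = FALSE)
      tot <- tot + sum((as.numeric(fwd$pred$value) - yva[idx])^2)
    }
    tot / val_data$n
  }

  with_seed(config$rng_seed, {
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample(train_data$n)
      tr_tot <- 0
      for (start in seq.int(1L, train_data$n, by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1L, train_data$n)]
        tape <- ad_tape(training = TRUE)
        pn <- ad_leaves(tape, model$params)
        fwd <- model_forward_batch(tape, pn, model, train_data, idx, training = TRUE)
        loss <- ad_mse(tape, fwd$pred, ytr[idx])
        if (!is.null(fwd$penalty)) {
          loss <- ad_scalar_sum(tape, list(loss, fwd$penalty), c(1, model$l2))
        }
        if (!is.finite(loss$value)) {
          stop("non-finite training loss at epoch ", epoch, ", batch starting ",
               start, " (lr = ", config$lr, ")")
        }
        ad_backward(tape, loss)
        model$params <- adam_step(st, model$params, ad_grads(pn))
        tr_tot <- tr_tot + loss$value * length(idx)
      }
      vl <- val_loss(model$params)
      n_epochs <- epoch
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  train_loss = tr_tot / train_data$n,
                                  val_loss = vl)
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                        tr_tot / train_data$n, vl))
      }
      if (vl < best$loss) {
        best <- list(loss = vl, params = model$params, epoch = epoch)
      } else if (epoch - best$epoch >= config$patience) {
        break
      }
    }
  })
  model$params <- best$params
  model$best_val_loss <- best$loss
  model$history <- do.call(rbind, hist[seq_len(n_epochs)])
  model$trained <- TRUE
  model
}

## ---- metrics ----

#' Root mean squared error
#' @param y,yhat numeric vectors of equal length (`n >= 1`).
#' @return RMSE in the units of `y` (kg/ha for yields).
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) < 1L) stop("need at least one observation")
  sqrt(mean((y - yhat)^2))
}

#' Coefficient of determination R-squared
#'
#' `1 - RSS/TSS` with TSS taken around the mean of the evaluation set itself,
#' so a predictor worse than that mean yields a negative value.
#'
#' @param y,yhat numeric vectors of equal length (`n >= 2`).
#' @return unitless value `<= 1`.
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) < 2L) stop("need at least two observations")
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("R-squared undefined for constant y")
  1 - sum((y - yhat)^2) / tss
}

#' Mean absolute percentage error
#' @param y,yhat numeric vectors of equal length; all `y` non-zero.
#' @return MAPE in percent.
#' @export
mape <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (any(y == 0)) stop("MAPE undefined when ground truth contains zeros")
  100 * mean(abs((y - yhat) / y))
}

#' Compute the three evaluation metrics at once
#' @param y,yhat numeric vectors.
#' @return list of class `metric_report`: `rmse`, `r_squared`, `mape_pct`, `n`.
#' @export
metric_report <- function(y, yhat) {
  structure(list(rmse = rmse(y, yhat), r_squared = r_squared(y, yhat),
                 mape_pct = mape(y, yhat), n = length(y)),
            class = "metric_report")
}
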