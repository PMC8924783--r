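#' Model specification for the 10-block 1-D convolutional classifier
#'
#' The backbone is ten blocks of convolution (valid padding, stride 1),
#' batch normalization and max-pooling, with filter counts growing
#' 8, 16, 16, 32, 32, 64, 64, 128, 128, 256 and kernel sizes
#' 11, 10, 10, 8, 9, 6, 7, 4, 5, 2, followed by a global max-pool over time
#' and a fully connected sigmoid unit emitting one eating probability per
#' window. Pooling sizes are derived automatically: each block halves the
#' sequence while the remaining length can still feed the downstream
#' kernels (at a 15000-sample input this pools by 2 after blocks 1-9); pass
#' `pools` to override.
#'
#' @param input_length Samples per window (e.g. 300 s x 50 Hz = 15000).
#' @param input_channels 3 (one sensor) or 6 (both sensors).
#' @param filters,kernels Per-block filter counts and kernel sizes; both
#'   must have length 10.
#' @param pools Optional per-block max-pool sizes.
#' @return A `wf_cnn_spec` list, including the derived per-block output
#'   lengths.
#' @export
cnn_spec <- function(input_length, input_channels = 3,
                     filters = c(8, 16, 16, 32, 32, 64, 64, 128, 128, 256),
                     kernels = c(11, 10, 10, 8, 9, 6, 7, 4, 5, 2),
                     pools = NULL) {
  if (length(filters) != 10 || length(kernels) != 10) {
    abort("configuration error: `filters` and `kernels` must each have length 10.",
          class = "wristfork_config_error")
  }
  if (!input_channels %in% c(3, 6)) {
    abort("configuration error: `input_channels` must be 3 or 6.",
          class = "wristfork_config_error")
  }
  stopifnot_scalar_number(input_length, "input_length", positive = TRUE)
  n_blocks <- length(kernels)
  if (is.null(pools)) {
    pools <- integer(n_blocks)
    len <- input_length
    # minimal input lengths if no further pooling happened
    min_rest <- rev(cumsum(rev(kernels - 1))) + 1
    for (b in seq_len(n_blocks)) {
      if (len < kernels[b]) {
        abort(sprintf(
          "configuration error: input length exhausted at block %d (need >= %d, have %d).",
          b, kernels[b], len), class = "wristfork_config_error")
      }
      len <- len - kernels[b] + 1
      need <- if (b < n_blocks) min_rest[b + 1] else 1
      pools[b] <- if (floor(len / 2) >= need) 2L else 1L
      len <- floor(len / pools[b])
    }
  } else {
    if (length(pools) != n_blocks) {
      abort("configuration error: `pools` must have one entry per block.",
            class = "wristfork_config_error")
    }
    len <- input_length
    for (b in seq_len(n_blocks)) {
      if (len < kernels[b]) {
        abort(sprintf(
          "configuration error: input length exhausted at block %d (need >= %d, have %d).",
          b, kernels[b], len), class = "wristfork_config_error")
      }
      len <- floor((len - kernels[b] + 1) / pools[b])
      if (len < 1) {
        abort(sprintf("configuration error: pooling empties block %d.", b),
              class = "wristfork_config_error")
      }
    }
  }
  lens <- integer(n_blocks)
  len <- input_length
  for (b in seq_len(n_blocks)) {
    len <- floor((len - kernels[b] + 1) / pools[b])
    lens[b] <- len
  }
  structure(list(
    input_length = as.integer(input_length),
    input_channels = as.integer(input_channels),
    filters = as.integer(filters),
    kernels = as.integer(kernels),
    pools = as.integer(pools),
    block_lengths = lens
  ), class = "wf_cnn_spec")
}

#' @export
print.wf_cnn_spec <- function(x, ...) {
  cat(sprintf("10-block 1-D CNN: input %d x %d\n", x$input_length, x$input_channels))
  cat(sprintf("  filters: %s\n", paste(x$filters, collapse = ",")))
  cat(sprintf("  kernels: %s\n", paste(x$kernels, collapse = ",")))
  cat(sprintf("  pools:   %s (then global max)\n", paste(x$pools, collapse = ",")))
  cat(sprintf("  parameters: %d\n", n_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters of a spec
#' @param spec A `wf_cnn_spec`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(spec) {
  ch <- c(spec$input_channels, spec$filters)
  conv <- sum(spec$kernels * ch[-length(ch)] * spec$filters + spec$filters)
  bn <- sum(2 * spec$filters)
  as.integer(conv + bn + spec$filters[length(spec$filters)] + 1)
}

#' Initialize network weights (Glorot uniform)
#'
#' Convolution kernels and the output unit draw from
#' `U(-sqrt(6/(fan_in + fan_out)), +sqrt(6/(fan_in + fan_out)))`; batch-norm
#' scales start at 1, shifts at 0, running statistics at (0, 1).
#'
#' @param spec A [cnn_spec()].
#' @param seed Optional seed; the same seed reproduces the initial weights.
#' @return A weights list consumed by [train_cnn()] / [predict_cnn()].
#' @export
init_cnn <- function(spec, seed = NULL) {
  with_seed(seed, {
    ch_in <- spec$input_channels
    blocks <- vector("list", length(spec$filters))
    for (b in seq_along(spec$filters)) {
      k <- spec$kernels[b]; ch_out <- spec$filters[b]
      fan_in <- k * ch_in; fan_out <- k * ch_out
      lim <- sqrt(6 / (fan_in + fan_out))
      blocks[[b]] <- list(
        W = matrix(runif(fan_in * ch_out, -lim, lim), fan_in, ch_out),
        b = rep(0, ch_out),
        gamma = rep(1, ch_out),
        beta = rep(0, ch_out),
        rmean = rep(0, ch_out),
        rvar = rep(1, ch_out)
      )
      ch_in <- ch_out
    }
    lim <- sqrt(6 / (ch_in + 1))
    list(blocks = blocks, w_out = runif(ch_in, -lim, lim), b_out = 0)
  })
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 3e-5, the full-scale
#'   setting; scaled-down experiments with few gradient updates want a
#'   larger rate).
#' @param epochs Training epochs (default 5).
#' @param batch_size Minibatch size (default 64).
#' @param restore_best Restore the weights from the epoch with the best
#'   validation performance (default `TRUE`).
#' @param best_metric `"loss"` (minimum validation loss) or `"auc"`.
#' @param finetune_epochs Epochs used when fine-tuning a personal model
#'   (default 2).
#' @param bn_momentum,bn_eps Batch-norm running-statistic momentum and
#'   variance floor.
#' @param seed Optional training seed (shuffling, augmentation draws).
#' @return A `wf_train_config` list.
#' @export
train_config <- function(learning_rate = 3e-5, epochs = 5, batch_size = 64,
                         restore_best = TRUE, best_metric = c("loss", "auc"),
                         finetune_epochs = 2, bn_momentum = 0.1,
                         bn_eps = 1e-5, seed = NULL) {
  stopifnot_scalar_number(learning_rate, "learning_rate", positive = TRUE)
  if (epochs < 0) abort("`epochs` must be >= 0.", class = "wristfork_config_error")
  structure(list(
    learning_rate = learning_rate, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), restore_best = restore_best,
    best_metric = match.arg(best_metric), finetune_epochs = as.integer(finetune_epochs),
    bn_momentum = bn_momentum, bn_eps = bn_eps, seed = seed
  ), class = "wf_train_config")
}

# flatten/apply helpers for the Adam state
adam_init <- function(weights) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(weights), v = zero_like(weights), t = 0L)
}

adam_update <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(w, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(w = w - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  for (b in seq_along(weights$blocks)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      r <- upd(weights$blocks[[b]][[nm]], grads$blocks[[b]][[nm]],
               state$m$blocks[[b]][[nm]], state$v$blocks[[b]][[nm]])
      weights$blocks[[b]][[nm]] <- r$w
      state$m$blocks[[b]][[nm]] <- r$m
      state$v$blocks[[b]][[nm]] <- r$v
    }
  }
  r <- upd(weights$w_out, grads$w_out, state$m$w_out, state$v$w_out)
  weights$w_out <- r$w; state$m$w_out <- r$m; state$v$w_out <- r$v
  r <- upd(weights$b_out, grads$b_out, state$m$b_out, state$v$b_out)
  weights$b_out <- r$w; state$m$b_out <- r$m; state$v$b_out <- r$v
  list(weights = weights, state = state)
}

# Assemble a (len, ch, n) cube from an (n, len, ch) array after per-window
# normalization and optional augmentation.
prepare_batch <- function(X, idx, transforms, augment) {
  n <- length(idx)
  len <- dim(X)[2]; ch <- dim(X)[3]
  out <- array(0, dim = c(len, ch, n))
  for (j in seq_len(n)) {
    w <- matrix(X[idx[j], , ], len, ch)
    if (augment) w <- apply_augmentation(w, transforms)
    w <- apply_normalization(w, transforms$normalization)
    out[, , j] <- w
  }
  out
}

#' Train one network on labeled windows
#'
#' Runs minibatch Adam on binary cross-entropy, applying the configured
#' augmentations on the fly to training windows only, and evaluates the
#' validation set after every epoch. With `restore_best` the returned
#' weights come from the epoch with the best validation performance.
#'
#' @param weights Initial weights from [init_cnn()].
#' @param spec The [cnn_spec()].
#' @param x Training signal array (windows x samples x channels), typically
#'   from [window_signals()] on an oversampled window set.
#' @param y Binary labels aligned with `x`.
#' @param val_x,val_y Validation windows at their original imbalance.
#' @param config A [train_config()].
#' @param transforms A [transform_config()].
#' @return List: `weights` (best or final), `history` (per-epoch tibble with
#'   training loss and validation loss/AUC), `best_epoch`.
#' @export
train_cnn <- function(weights, spec, x, y, val_x, val_y,
                      config = train_config(),
                      transforms = transform_config()) {
  if (length(y) == 0 || length(val_y) == 0) {
    abort("empty training or validation set.", class = "wristfork_usage_error")
  }
  with_seed(config$seed, {
    history <- list()
    best <- list(weights = weights, value = Inf, epoch = 0L)
    state <- adam_init(weights)
    n <- length(y)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        xb <- prepare_batch(x, idx, transforms, augment = TRUE)
        res <- cnn_pass(weights, xb, y[idx], spec$kernels, spec$pools,
                        training = TRUE, compute_grad = TRUE,
                        bn_momentum = config$bn_momentum, bn_eps = config$bn_eps)
        for (b in seq_along(weights$blocks)) {
          weights$blocks[[b]]$rmean <- res$bn_stats[[b]]$rmean
          weights$blocks[[b]]$rvar <- res$bn_stats[[b]]$rvar
        }
        au <- adam_update(weights, res$grads, state, config$learning_rate)
        weights <- au$weights; state <- au$state
        losses <- c(losses, res$loss)
      }
      val_scores <- predict_cnn(weights, spec, val_x, transforms)
      vp <- pmin(pmax(val_scores, 1e-12), 1 - 1e-12)
      val_loss <- -mean(val_y * log(vp) + (1 - val_y) * log(1 - vp))
      val_auc <- if (length(unique(val_y)) > 1) roc_auc(val_scores, val_y) else NA_real_
      crit <- if (config$best_metric == "loss") val_loss else -val_auc
      if (config$restore_best && is.finite(crit) && crit < best$value) {
        best <- list(weights = weights, value = crit, epoch = epoch)
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = mean(losses),
        val_loss = val_loss, val_auc = val_auc
      )
    }
    final <- if (config$restore_best && best$epoch > 0) best$weights else weights
    list(weights = final,
         history = dplyr::bind_rows(history),
         best_epoch = if (config$restore_best && best$epoch > 0) best$epoch
                      else config$epochs)
  })
}

#' Score windows with a trained network
#'
#' Pure inference: the evaluation path applies only the configured
#' normalization (never augmentation) and uses the batch-norm running
#' statistics, so repeated calls on the same input give identical scores.
#'
#' @param weights Trained weights.
#' @param spec The [cnn_spec()].
#' @param x Signal array (windows x samples x channels).
#' @param transforms A [transform_config()] (only `normalization` is used).
#' @param chunk Windows per forward pass (memory bound).
#' @return Numeric vector of eating probabilities in \[0, 1\].
#' @export
predict_cnn <- function(weights, spec, x, transforms = transform_config(),
                        chunk = 256L) {
  n <- dim(x)[1]
  if (n == 0) return(numeric(0))
  scores <- numeric(n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    xb <- prepare_batch(x, idx, transforms, augment = FALSE)
    res <- cnn_pass(weights, xb, numeric(0), spec$kernels, spec$pools,
                    training = FALSE, compute_grad = FALSE,
                    bn_momentum = 0.1, bn_eps = 1e-5)
    scores[idx] <- res$scores
  }
  scores
}
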