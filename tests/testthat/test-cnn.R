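tiny_spec <- function() cnn_spec(input_length = 64, input_channels = 3)

rand_windows <- function(n, len = 64, ch = 3, seed = 1) {
  set.seed(seed)
  array(rnorm(n * len * ch), dim = c(n, len, ch))
}

test_that("the spec enforces the published architecture shape", {
  spec <- cnn_spec(input_length = 15000)
  expect_equal(spec$filters, c(8, 16, 16, 32, 32, 64, 64, 128, 128, 256))
  expect_equal(spec$kernels, c(11, 10, 10, 8, 9, 6, 7, 4, 5, 2))
  # halving cascade through the first nine blocks at full length
  expect_equal(spec$pools[1:9], rep(2L, 9))
  expect_equal(spec$block_lengths[10] >= 1, TRUE)

  expect_error(cnn_spec(15000, filters = c(8, 16)),
               class = "wristfork_config_error")
  expect_error(cnn_spec(15000, input_channels = 4),
               class = "wristfork_config_error")
  # too-short input names the failing block
  expect_error(cnn_spec(input_length = 16), "block",
               class = "wristfork_config_error")
})

test_that("initialization is reproducible and the forward pass is a pure function", {
  spec <- tiny_spec()
  w1 <- init_cnn(spec, seed = 7)
  w2 <- init_cnn(spec, seed = 7)
  expect_identical(w1, w2)
  w3 <- init_cnn(spec, seed = 8)
  expect_false(identical(w1$blocks[[1]]$W, w3$blocks[[1]]$W))

  x <- rand_windows(6)
  s1 <- predict_cnn(w1, spec, x)
  s2 <- predict_cnn(w1, spec, x)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))
})

test_that("analytic gradients match central finite differences", {
  spec <- tiny_spec()
  w <- init_cnn(spec, seed = 1)
  x <- rand_windows(5, seed = 3)
  xb <- aperm(x, c(2, 3, 1))
  y <- c(1, 0, 1, 1, 0)
  pass <- function(w) {
    wristfork:::cnn_pass(w, xb, y, spec$kernels, spec$pools,
                         training = TRUE, compute_grad = TRUE,
                         bn_momentum = 0.1, bn_eps = 1e-5)
  }
  res <- pass(w)
  expect_true(is.finite(res$loss))
  eps <- 1e-5
  set.seed(9)
  for (b in c(2, 5, 9)) {
    for (nm in c("W", "gamma", "beta")) {
      i <- sample(length(w$blocks[[b]][[nm]]), 1)
      wp <- w; wp$blocks[[b]][[nm]][i] <- wp$blocks[[b]][[nm]][i] + eps
      wm <- w; wm$blocks[[b]][[nm]][i] <- wm$blocks[[b]][[nm]][i] - eps
      num <- (pass(wp)$loss - pass(wm)$loss) / (2 * eps)
      expect_equal(res$grads$blocks[[b]][[nm]][i], num, tolerance = 1e-4)
    }
  }
  wp <- w; wp$b_out <- wp$b_out + eps
  wm <- w; wm$b_out <- wm$b_out - eps
  expect_equal(res$grads$b_out, (pass(wp)$loss - pass(wm)$loss) / (2 * eps),
               tolerance = 1e-6)
})

test_that("training reduces loss on a separable toy problem", {
  spec <- tiny_spec()
  set.seed(20)
  n <- 60
  y <- rep(0:1, each = n / 2)
  x <- array(rnorm(n * 64 * 3, sd = 0.3), dim = c(n, 64, 3))
  # positives carry a burst in the middle of channel 1
  for (i in which(y == 1)) x[i, 25:40, 1] <- x[i, 25:40, 1] + 2
  fit <- train_cnn(init_cnn(spec, seed = 1), spec, x, y, x, y,
                   config = train_config(learning_rate = 1e-3, epochs = 6,
                                         batch_size = 16, bn_momentum = 0.3,
                                         seed = 2),
                   transforms = transform_config(normalization = "centering",
                                                 scale = FALSE))
  expect_lt(tail(fit$history$val_loss, 1), fit$history$val_loss[1])
  expect_gt(tail(fit$history$val_auc, 1), 0.9)
})

test_that("best-epoch restore returns the weights of the best validation epoch", {
  spec <- tiny_spec()
  set.seed(21)
  n <- 40
  y <- rep(0:1, each = n / 2)
  x <- array(rnorm(n * 64 * 3, sd = 0.5), dim = c(n, 64, 3))
  for (i in which(y == 1)) x[i, 30:40, 2] <- x[i, 30:40, 2] + 1.5
  # aggressive learning rate so validation loss is non-monotone
  cfg <- train_config(learning_rate = 2e-2, epochs = 5, batch_size = 8,
                      seed = 3)
  tr <- transform_config(normalization = "centering", scale = FALSE)
  fit <- train_cnn(init_cnn(spec, seed = 2), spec, x, y, x[1:20, , , drop = FALSE],
                   y[1:20], cfg, tr)
  expect_equal(fit$best_epoch, which.min(fit$history$val_loss))
  # the restored weights reproduce exactly the validation loss recorded at
  # the best epoch
  val_scores <- predict_cnn(fit$weights, spec, x[1:20, , , drop = FALSE], tr)
  vp <- pmin(pmax(val_scores, 1e-12), 1 - 1e-12)
  vl <- -mean(y[1:20] * log(vp) + (1 - y[1:20]) * log(1 - vp))
  expect_equal(vl, min(fit$history$val_loss), tolerance = 1e-10)
})

test_that("training is deterministic under a fixed seed", {
  spec <- tiny_spec()
  set.seed(22)
  n <- 24
  y <- rep(0:1, n / 2)
  x <- array(rnorm(n * 64 * 3), dim = c(n, 64, 3))
  cfg <- train_config(learning_rate = 1e-3, epochs = 2, batch_size = 8, seed = 5)
  f1 <- train_cnn(init_cnn(spec, seed = 1), spec, x, y, x, y, cfg)
  f2 <- train_cnn(init_cnn(spec, seed = 1), spec, x, y, x, y, cfg)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
})
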