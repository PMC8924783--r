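test_that("AUC equals the exhaustive pairwise estimate", {
  set.seed(10)
  for (i in 1:100) {
    n <- sample(6:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    expect_equal(roc_auc(scores, labels), auc_bruteforce(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC and AUPRC agree with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- runif(n)
    ref <- as.numeric(suppressMessages(pROC::auc(labels, scores,
                                                 direction = "<")))
    expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-9)
    expect_equal(pr_auc(scores, labels), auprc_reference(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(12)
  scores <- runif(60)
  labels <- sample(0:1, 60, replace = TRUE, prob = c(0.8, 0.2))
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(qlogis(scores), labels), a, tolerance = 1e-12)
  expect_equal(roc_auc(scores^3 + 2, labels), a, tolerance = 1e-12)
})

test_that("separated scores give AUC and AUPRC of 1; baseline is prevalence", {
  labels <- c(rep(0, 18), rep(1, 2))
  scores <- c(runif(18, 0, 0.4), runif(2, 0.6, 1))
  m <- window_metrics(data.frame(score = scores, label = labels))
  expect_equal(m$auc, 1)
  expect_equal(m$auprc, 1)
  expect_equal(m$auprc_baseline, 0.1)
  # an uninformative constant scorer earns the baseline
  expect_equal(pr_auc(rep(0.5, 20), labels), 0.1, tolerance = 1e-12)
})

test_that("weighted accuracy matches the class-rebalanced hand arithmetic", {
  # TP = 8, FN = 2, TN = 90, FP = 10 -> w = 10, (10*8 + 90)/(10*10 + 100)
  scores <- c(rep(0.9, 8), rep(0.1, 2), rep(0.1, 90), rep(0.9, 10))
  labels <- c(rep(1, 10), rep(0, 100))
  m <- window_metrics(data.frame(score = scores, label = labels))
  expect_equal(m$tp, 8); expect_equal(m$fn, 2)
  expect_equal(m$tn, 90); expect_equal(m$fp, 10)
  expect_equal(m$acc_weighted, 0.85, tolerance = 1e-12)
  expect_equal(m$precision, 8 / 18)
  expect_equal(m$recall, 0.8)
})

test_that("weighted F1 reduces to macro F1 on balanced classes", {
  set.seed(13)
  scores <- runif(200)
  labels <- rep(0:1, each = 100)
  m <- window_metrics(data.frame(score = scores, label = labels))
  cc <- wristfork:::confusion_counts(scores, labels, 0.5)
  f1_pos <- 2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn)
  f1_neg <- 2 * cc$tn / (2 * cc$tn + cc$fn + cc$fp)
  expect_equal(m$f1_weighted, (f1_pos + f1_neg) / 2, tolerance = 1e-12)
})

test_that("single-class inputs leave AUC undefined but keep other metrics", {
  expect_warning(m <- window_metrics(data.frame(score = runif(5),
                                                label = rep(0, 5))),
                 "one class")
  expect_true(is.na(m$auc))
  expect_true(is.na(m$auprc))
  expect_false(is.na(m$precision))
})

test_that("identical scorers sit in the symmetric p-value band, dominance at 0", {
  set.seed(14)
  n <- 400
  labels <- sample(0:1, n, replace = TRUE, prob = c(0.8, 0.2))
  s <- runif(n)
  d <- data.frame(score_a = s, score_b = s, label = labels)
  res <- resample_compare(d, n_pos = 30, repeats = 40, seed = 1)
  expect_true(all(res$p_value == 0.5))

  # a strictly dominates b: same ordering quality, but b degraded on a
  # subset of windows
  good <- plogis(3 * (labels - 0.5) + rnorm(n, sd = 0.5))
  bad <- runif(n)
  d2 <- data.frame(score_a = good, score_b = bad, label = labels)
  res2 <- resample_compare(d2, n_pos = 30, repeats = 40, seed = 2)
  expect_lt(res2$p_value[res2$metric == "auc"], 0.05)
})

test_that("the resampling draw preserves the class imbalance ratio", {
  set.seed(15)
  labels <- c(rep(1, 50), rep(0, 500))
  d <- data.frame(score_a = runif(550), score_b = runif(550), label = labels)
  expect_message(
    res <- resample_compare(d, n_pos = 100, repeats = 5, seed = 3),
    "replacement"
  )
  expect_equal(nrow(res), 2)
})

test_that("a known AUC gap is detected by the resampling comparison", {
  set.seed(16)
  n <- 6000
  labels <- sample(0:1, n, replace = TRUE, prob = c(0.7, 0.3))
  # scorer a: higher signal-to-noise than b
  score_a <- plogis(1.2 * (labels - 0.5) + rnorm(n, sd = 0.8))
  score_b <- plogis(0.7 * (labels - 0.5) + rnorm(n, sd = 0.8))
  d <- data.frame(score_a, score_b, label = labels)
  res <- resample_compare(d, n_pos = 1000, repeats = 50, metrics = "auc",
                          seed = 4)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$mean_a, res$mean_b)
})
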