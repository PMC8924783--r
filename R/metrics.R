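#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator: the probability that a uniformly
#' chosen positive outscores a uniformly chosen negative, counting ties as
#' one half.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1 or logical).
#' @return AUC in \[0, 1\]; `NA` with a warning when only one class is
#'   present.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    warn("AUC undefined: only one class present.")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Average-precision estimator: sum over descending-score cut points of
#' precision times the recall increment (ties handled as one block). The
#' baseline of an uninformative scorer is the positive prevalence.
#'
#' @inheritParams roc_auc
#' @return AUPRC in \[0, 1\]; `NA` with a warning when only one class is
#'   present.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    warn("AUPRC undefined: only one class present.")
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # collapse tied scores into blocks
  block <- cumsum(c(TRUE, diff(s) != 0))
  tp_b <- tapply(y, block, sum)
  n_b <- tapply(rep(1L, length(y)), block, sum)
  tp <- cumsum(tp_b); fp <- cumsum(n_b) - tp
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(prec * diff(c(0, rec)))
}

confusion_counts <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(as.logical(labels))
  pred <- as.integer(scores > threshold)
  list(
    tp = sum(pred == 1L & labels == 1L),
    fp = sum(pred == 1L & labels == 0L),
    tn = sum(pred == 0L & labels == 0L),
    fn = sum(pred == 0L & labels == 1L)
  )
}

#' Window-level metric suite for imbalanced binary scores
#'
#' Computes AUC, AUPRC and its prevalence baseline, and the thresholded
#' confusion metrics: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, weighted
#' F1 (per-class F1 averaged with class-proportion weights
#' `w_i = n_i / n`), and weighted accuracy
#' `(w*TP + TN) / (w*(TP+FN) + TN + FP)` with `w = #negatives / #positives`,
#' the class-rebalanced accuracy convention used in wrist-sensor eating
#' detection studies.
#'
#' @param data Data frame of scored windows.
#' @param score,label Column names (strings) holding the score in \[0, 1\]
#'   and the binary label.
#' @param threshold Decision threshold for the confusion-based metrics
#'   (default 0.5).
#' @return One-row tibble: `n`, `prevalence`, `auc`, `auprc`,
#'   `auprc_baseline`, `precision`, `recall`, `f1_weighted`, `acc_weighted`,
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
window_metrics <- function(data, score = "score", label = "label",
                           threshold = 0.5) {
  s <- data[[score]]; y <- as.integer(as.logical(data[[label]]))
  if (length(s) == 0) abort("no scored windows.", class = "wristfork_usage_error")
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  cc <- confusion_counts(s, y, threshold)
  prec <- if (cc$tp + cc$fp > 0) cc$tp / (cc$tp + cc$fp) else 0
  rec <- if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else 0
  f1_pos <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  prec0 <- if (cc$tn + cc$fn > 0) cc$tn / (cc$tn + cc$fn) else 0
  rec0 <- if (cc$tn + cc$fp > 0) cc$tn / (cc$tn + cc$fp) else 0
  f1_neg <- if (prec0 + rec0 > 0) 2 * prec0 * rec0 / (prec0 + rec0) else 0
  n <- length(y)
  f1_w <- (n_pos * f1_pos + n_neg * f1_neg) / n
  acc_w <- if (n_pos > 0) {
    w <- n_neg / n_pos
    (w * cc$tp + cc$tn) / (w * (cc$tp + cc$fn) + cc$tn + cc$fp)
  } else {
    NA_real_
  }
  auc <- if (n_pos > 0 && n_neg > 0) roc_auc(s, y) else { warn("AUC undefined: only one class present."); NA_real_ }
  auprc <- if (n_pos > 0 && n_neg > 0) pr_auc(s, y) else NA_real_
  tibble::tibble(
    n = n, prevalence = n_pos / n,
    auc = auc, auprc = auprc, auprc_baseline = n_pos / n,
    precision = prec, recall = rec,
    f1_weighted = f1_w, acc_weighted = acc_w,
    tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn
  )
}

#' Paired resampling comparison of two scorers
#'
#' Compares two models that scored the same windows, mirroring the
#' resampling significance scheme used for imbalanced window sets: in each
#' repeat, draw `n_pos` positive windows and `n_pos * R` negatives (`R` the
#' negative:positive imbalance ratio of the full set, so the draw preserves
#' the original imbalance), compute each metric for both scorers on that
#' common draw, and report the one-sided p-value as the fraction of repeats
#' in which scorer `a` fails to beat scorer `b`.
#'
#' @param data Data frame with both scores and the shared labels.
#' @param score_a,score_b,label Column names.
#' @param n_pos Positive windows per draw (default 1500; sampled with
#'   replacement, with a message, when fewer are available).
#' @param repeats Number of resampling repeats (default 100).
#' @param metrics Metrics to compare (columns of [window_metrics()]).
#' @param continuity Add-one continuity correction `(k+1)/(repeats+1)`.
#' @param seed Optional seed.
#' @return Tibble with `metric`, `mean_a`, `mean_b`, `p_value`.
#' @export
resample_compare <- function(data, score_a = "score_a", score_b = "score_b",
                             label = "label", n_pos = 1500, repeats = 100,
                             metrics = c("auc", "auprc"), continuity = FALSE,
                             seed = NULL) {
  y <- as.integer(as.logical(data[[label]]))
  pos_idx <- which(y == 1L); neg_idx <- which(y == 0L)
  if (length(pos_idx) == 0 || length(neg_idx) == 0) {
    abort("both classes required.", class = "wristfork_usage_error")
  }
  ratio <- length(neg_idx) / length(pos_idx)
  n_neg <- max(1L, round(n_pos * ratio))
  replace_pos <- length(pos_idx) < n_pos
  replace_neg <- length(neg_idx) < n_neg
  if (replace_pos || replace_neg) {
    inform("fewer windows than requested; resampling with replacement.")
  }
  with_seed(seed, {
    vals_a <- matrix(NA_real_, repeats, length(metrics))
    vals_b <- matrix(NA_real_, repeats, length(metrics))
    for (r in seq_len(repeats)) {
      ip <- sample(pos_idx, n_pos, replace = replace_pos)
      ineg <- sample(neg_idx, n_neg, replace = replace_neg)
      idx <- c(ip, ineg)
      suppressWarnings({
        ma <- window_metrics(data.frame(score = data[[score_a]][idx], label = y[idx]))
        mb <- window_metrics(data.frame(score = data[[score_b]][idx], label = y[idx]))
      })
      vals_a[r, ] <- unlist(ma[1, metrics])
      vals_b[r, ] <- unlist(mb[1, metrics])
    }
    # ties count half, so two equivalent scorers sit at p ~ 0.5
    k <- colSums(vals_a < vals_b) + 0.5 * colSums(vals_a == vals_b)
    p <- if (continuity) (k + 1) / (repeats + 1) else k / repeats
    tibble::tibble(
      metric = metrics,
      mean_a = colMeans(vals_a),
      mean_b = colMeans(vals_b),
      p_value = p
    )
  })
}
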