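# Hand-constructed sensor days with exactly known structure, independent of
# the package's own generator.
#
# `meals` is a data frame of (start_s, end_s, retro) in seconds from the
# day's first sample; `gaps` a data frame of (start_s, end_s) recording
# breaks. Signals are flat noise unless `signal_fn` is given.
build_day <- function(duration_s, rate = 1, meals = NULL, gaps = NULL,
                      participant_id = "T01", date = "2026-01-05",
                      noise_sd = 0.1, signal_fn = NULL, seed = 1) {
  set.seed(seed)
  tsec <- seq(0, duration_s - 1 / rate, by = 1 / rate)
  keep <- rep(TRUE, length(tsec))
  if (!is.null(gaps)) {
    for (g in seq_len(nrow(gaps))) {
      keep <- keep & !(tsec >= gaps$start_s[g] & tsec < gaps$end_s[g])
    }
  }
  tsec <- tsec[keep]
  n <- length(tsec)
  sesid <- if (is.null(gaps)) rep(1L, n) else 1L + findInterval(tsec, sort(gaps$end_s))
  sig <- matrix(rnorm(n * 6, sd = noise_sd), n, 6)
  colnames(sig) <- c("accl_x", "accl_y", "accl_z", "gyro_x", "gyro_y", "gyro_z")
  if (!is.null(signal_fn)) sig <- signal_fn(tsec, sig)
  tag <- integer(n); timely <- integer(n); retro <- rep(NA_real_, n)
  if (!is.null(meals)) {
    for (m in seq_len(nrow(meals))) {
      idx <- which(tsec >= meals$start_s[m] & tsec < meals$end_s[m])
      tag[idx] <- 1L
      if (isTRUE(meals$retro[m])) retro[idx] <- 1 else timely[idx] <- 1L
    }
  }
  epoch_ms <- as.numeric(as.POSIXct(paste(date, "00:00:00"), tz = "UTC")) * 1000 +
    8 * 3600 * 1000
  samples <- tibble::tibble(
    ts = epoch_ms + tsec * 1000, tod = 8 * 3600 + tsec, sesid = sesid
  )
  samples <- dplyr::bind_cols(samples, tibble::as_tibble(sig))
  for (u in c("fork", "knife", "spoon", "glass", "chopstick", "hand")) {
    samples[[u]] <- 0L
  }
  samples$tag <- tag
  samples$tagTimely <- timely
  samples$tagRetro <- retro
  sensor_day(samples, participant_id, date, validate = FALSE)
}

# independent per-window label re-derivation (the windowing oracle):
# loops over raw samples with none of the cumulative-sum machinery
relabel_window <- function(day, start_idx, end_idx, rate, window_seconds,
                           min_meal_seconds, meals = extract_meals(day)) {
  rows <- start_idx:end_idx
  if (length(unique(day$sesid[rows])) > 1) return(-1L)
  retro_set <- !is.na(day$tagRetro[rows]) & day$tagRetro[rows] != 0
  if (any(retro_set)) return(-1L)
  if (nrow(meals) > 0) {
    w_lo <- day$ts[start_idx]
    w_hi <- day$ts[end_idx]
    for (m in seq_len(nrow(meals))) {
      dur_s <- (meals$end_ts[m] - meals$start_ts[m]) / 1000
      overlaps <- meals$start_ts[m] <= w_hi && meals$end_ts[m] > w_lo
      if (overlaps && dur_s < min_meal_seconds) return(-1L)
    }
  }
  if (sum(day$tag[rows]) / rate > window_seconds / 2) 1L else 0L
}

# brute-force pairwise AUC (the metric oracle)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# independent average-precision computation (point by point, no blocking)
auprc_reference <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  n_pos <- sum(y)
  ap <- 0; tp <- 0; prev_rec <- 0
  i <- 1
  while (i <= length(y)) {
    j <- i
    while (j < length(y) && s[j + 1] == s[i]) j <- j + 1
    tp <- tp + sum(y[i:j])
    prec <- tp / j
    rec <- tp / n_pos
    ap <- ap + prec * (rec - prev_rec)
    prev_rec <- rec
    i <- j + 1
  }
  ap
}
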