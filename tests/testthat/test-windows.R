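test_that("window counts follow floor((L - window)/step) + 1", {
  # a 3600-s single-session day at the default 300/20 windowing
  day <- build_day(3600, rate = 1)
  expect_equal(nrow(make_windows(day)), 166)

  # 300-s day: exactly one window, label 0
  day1 <- build_day(300, rate = 1)
  w1 <- make_windows(day1)
  expect_equal(nrow(w1), 1)
  expect_equal(w1$label, 0L)

  # shorter than a window: empty set
  expect_equal(nrow(make_windows(build_day(200, rate = 1))), 0)

  set.seed(7)
  for (L in sample(300:5000, 30)) {
    day <- build_day(L, rate = 1, seed = L)
    expect_equal(nrow(make_windows(day)), floor((L - 300) / 20) + 1)
  }
})

test_that("the half-window meal rule is strict: 151 s -> 1, 150 s -> 0", {
  # long meals entering the first 300-s window by 151 vs 150 seconds
  d151 <- build_day(600, rate = 1,
                    meals = data.frame(start_s = 149, end_s = 600, retro = FALSE))
  expect_equal(make_windows(d151)$label[1], 1L)
  d150 <- build_day(600, rate = 1,
                    meals = data.frame(start_s = 150, end_s = 600, retro = FALSE))
  expect_equal(make_windows(d150)$label[1], 0L)
})

test_that("windows spanning two sessions are labeled -1", {
  day <- build_day(900, rate = 1, gaps = data.frame(start_s = 400, end_s = 430))
  w <- make_windows(day, step_seconds = 20)
  crossing <- day$sesid[w$start_idx] != day$sesid[w$end_idx]
  expect_true(any(crossing))
  expect_true(all(w$label[crossing] == -1L))
  expect_true(all(w$label[!crossing] == 0L))
})

test_that("retro overlap and short meals force -1", {
  d_retro <- build_day(600, rate = 1,
                       meals = data.frame(start_s = 200, end_s = 500, retro = TRUE))
  w <- make_windows(d_retro)
  overlaps <- w$end_ts > d_retro$ts[201] & w$start_ts < d_retro$ts[500]
  expect_true(all(w$label[overlaps] == -1L))

  d_short <- build_day(600, rate = 1,
                       meals = data.frame(start_s = 250, end_s = 350, retro = FALSE))
  w2 <- make_windows(d_short)   # 100-s meal < 180-s minimum
  overlaps2 <- w2$end_ts > d_short$ts[251] & w2$start_ts < d_short$ts[350]
  expect_true(all(w2$label[overlaps2] == -1L))
  expect_true(all(w2$label[!overlaps2] == 0L))
})

test_that("the labeler agrees with an independent per-window re-derivation", {
  set.seed(101)
  for (rep in 1:60) {
    L <- sample(400:2500, 1)
    n_meals <- sample(0:3, 1)
    meals <- if (n_meals > 0) {
      starts <- sort(sample(seq(10, L - 200, by = 10), n_meals))
      data.frame(
        start_s = starts,
        end_s = pmin(starts + sample(c(60, 120, 200, 400), n_meals, replace = TRUE),
                     L - 5),
        retro = sample(c(TRUE, FALSE), n_meals, replace = TRUE, prob = c(0.2, 0.8))
      )
    } else NULL
    if (!is.null(meals) && n_meals > 1 &&
        any(meals$start_s[-1] <= meals$end_s[-n_meals] + 1)) next
    gaps <- if (runif(1) < 0.3) data.frame(start_s = L / 2, end_s = L / 2 + 40) else NULL
    day <- build_day(L, rate = 1, meals = meals, gaps = gaps, seed = rep)
    w <- make_windows(day)
    if (nrow(w) == 0) next
    oracle <- vapply(seq_len(nrow(w)), function(i) {
      relabel_window(day, w$start_idx[i], w$end_idx[i], rate = 1,
                     window_seconds = 300, min_meal_seconds = 180)
    }, integer(1))
    expect_identical(w$label, oracle)
  }
})

test_that("labels ignore the signal channels entirely", {
  meals <- data.frame(start_s = 100, end_s = 400, retro = FALSE)
  day <- build_day(900, rate = 1, meals = meals, seed = 1)
  day2 <- day
  for (col in c("accl_x", "accl_y", "accl_z", "gyro_x", "gyro_y", "gyro_z")) {
    day2[[col]] <- rnorm(nrow(day2), sd = 100)
  }
  expect_identical(make_windows(day)$label, make_windows(day2)$label)
})

test_that("oversampling balances classes exactly and adds only duplicates", {
  set.seed(5)
  for (rep in 1:25) {
    n_pos <- sample(3:40, 1); n_neg <- n_pos + sample(0:200, 1)
    win <- tibble::tibble(
      participant_id = "X", date = as.Date("2026-01-05"),
      start_ts = seq_len(n_pos + n_neg) * 1000,
      end_ts = seq_len(n_pos + n_neg) * 1000 + 300000,
      label = sample(c(rep(1L, n_pos), rep(0L, n_neg)))
    )
    bal <- oversample_windows(win, seed = rep)
    expect_equal(sum(bal$label == 1), sum(bal$label == 0))
    expect_equal(sum(bal$label == 0), n_neg)
    # originals untouched, additions are copies of existing positives
    expect_equal(as.data.frame(bal[seq_len(nrow(win)), c("start_ts", "label")]),
                 as.data.frame(win[, c("start_ts", "label")]))
    extra <- bal[-seq_len(nrow(win)), ]
    expect_true(all(extra$label == 1))
    expect_true(all(extra$start_ts %in% win$start_ts[win$label == 1]))
    # distinct windows unchanged by the draw
    expect_setequal(unique(bal$start_ts), unique(win$start_ts))
  }
})

test_that("oversampling edge cases: zero positives error, surplus warns", {
  neg_only <- tibble::tibble(label = rep(0L, 5), start_ts = 1:5)
  expect_error(oversample_windows(neg_only), class = "wristfork_usage_error")
  surplus <- tibble::tibble(label = c(1L, 1L, 1L, 0L), start_ts = 1:4)
  expect_warning(out <- oversample_windows(surplus), "outnumber")
  expect_equal(nrow(out), 4)
  has_excluded <- tibble::tibble(label = c(1L, 0L, -1L), start_ts = 1:3)
  expect_error(oversample_windows(has_excluded), class = "wristfork_usage_error")
})

test_that("the oversampling arithmetic matches the published window totals", {
  # 282,942 windows of which 13,498 positive: the balancing draw must add
  # the negative-positive difference
  n_pos <- 13498; n_neg <- 282942 - 13498
  expect_equal(n_neg - n_pos, 255946)
})

test_that("window signal extraction returns the right slabs", {
  day <- build_day(400, rate = 2)
  w <- make_windows(day, window_seconds = 100, step_seconds = 50)
  sig <- window_signals(day, w, channels = "both")
  expect_equal(dim(sig), c(nrow(w), 200, 6))
  expect_equal(sig[2, , 4], day$gyro_x[w$start_idx[2]:w$end_idx[2]])
})
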