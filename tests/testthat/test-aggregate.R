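ms <- function(min) min * 60000

# a scored-window stream at a given stride covering [0, hours) hours
make_stream <- function(hours, stride_s = 10, score = 0) {
  starts <- seq(0, hours * 3600 - stride_s, by = stride_s) * 1000
  tibble::tibble(start_ts = starts, end_ts = starts + ms(5),
                 score = rep_len(score, length(starts)))
}

test_that("meal region scores are the mean of their member windows", {
  meals <- tibble::tibble(participant_id = "A", date = as.Date("2026-01-05"),
                          start_ts = ms(100), end_ts = ms(112),
                          retrospective = FALSE, utensils = "fork")
  # three windows with midpoints inside the meal, two outside
  sw <- tibble::tibble(
    participant_id = "A", date = as.Date("2026-01-05"),
    start_ts = c(ms(100), ms(103), ms(106), ms(300), ms(320)),
    end_ts = c(ms(105), ms(108), ms(111), ms(305), ms(325)),
    score = c(0.2, 0.4, 0.6, 0.1, 0.3)
  )
  rs <- score_meals(sw, meals, seed = 1)
  meal_row <- rs[rs$is_meal, ]
  expect_equal(meal_row$mean_score, 0.4)
  expect_equal(meal_row$n_windows, 3L)
  neg <- rs[!rs$is_meal, ]
  expect_equal(nrow(neg), 1)
  expect_equal(neg$end_ts - neg$start_ts, ms(12))
})

test_that("matched negatives reproduce the meal length multiset and avoid buffers", {
  set.seed(30)
  day <- as.Date("2026-01-05")
  meals <- tibble::tibble(
    participant_id = "A", date = day,
    start_ts = c(ms(60), ms(250), ms(400), ms(520), ms(600)),
    end_ts = c(ms(75), ms(258), ms(420), ms(535), ms(612)),
    retrospective = FALSE, utensils = ""
  )
  starts <- seq(0, ms(700), by = ms(1) / 3)
  sw <- tibble::tibble(participant_id = "A", date = day, start_ts = starts,
                       end_ts = starts + ms(5), score = runif(length(starts)))
  rs <- score_meals(sw, meals, buffer_minutes = 10, seed = 2)
  neg <- rs[!rs$is_meal, ]
  expect_equal(nrow(neg), 5)
  expect_equal(sort(neg$end_ts - neg$start_ts),
               sort(meals$end_ts - meals$start_ts))
  for (i in seq_len(nrow(neg))) {
    expect_false(any(neg$start_ts[i] < meals$end_ts + ms(10) &
                       neg$end_ts[i] > meals$start_ts - ms(10)))
  }
  # reproducible under the seed
  rs2 <- score_meals(sw, meals, buffer_minutes = 10, seed = 2)
  expect_identical(rs$start_ts, rs2$start_ts)
})

test_that("negative-region placement fails loudly when there is no room", {
  meals <- tibble::tibble(participant_id = "A", date = as.Date("2026-01-05"),
                          start_ts = ms(10), end_ts = ms(50),
                          retrospective = FALSE, utensils = "")
  sw <- tibble::tibble(participant_id = "A", date = as.Date("2026-01-05"),
                       start_ts = seq(ms(0), ms(60), by = ms(1)),
                       end_ts = seq(ms(0), ms(60), by = ms(1)) + ms(5),
                       score = 0.5)
  expect_error(score_meals(sw, meals, seed = 1), "negative",
               class = "wristfork_usage_error")
})

test_that("perfect window separation yields meal-level AUC 1", {
  set.seed(31)
  day <- as.Date("2026-01-05")
  meals <- tibble::tibble(participant_id = "A", date = day,
                          start_ts = c(ms(100), ms(300)),
                          end_ts = c(ms(115), ms(318)),
                          retrospective = FALSE, utensils = "")
  starts <- seq(0, ms(500), by = ms(1) / 3)
  in_meal <- sapply(starts + ms(2.5), function(m) {
    any(m >= meals$start_ts & m < meals$end_ts)
  })
  sw <- tibble::tibble(participant_id = "A", date = day, start_ts = starts,
                       end_ts = starts + ms(5),
                       score = ifelse(in_meal, 0.9, 0.05))
  rs <- score_meals(sw, meals, seed = 3)
  expect_equal(roc_auc(rs$mean_score, rs$is_meal), 1)
})

test_that("one hour of 10-second steps yields 360 candidate chunks", {
  stream <- make_stream(1)
  expect_equal(nrow(stream), 360)
  sc <- wristfork:::span_counts(stream, call_config())
  expect_equal(nrow(sc), 360)
})

test_that("call logic honors the strict > N rule", {
  cfg <- call_config(score_cutoff = 0.3, n_windows = 3, horizon_minutes = 5)
  # all-zero scores: no calls
  expect_equal(nrow(detect_calls(make_stream(2), cfg)), 0)

  # exactly 3 above-cutoff windows in the horizon: no call
  s3 <- make_stream(1)
  s3$score[c(10, 15, 20)] <- 0.9
  expect_equal(nrow(detect_calls(s3, cfg)), 0)

  # 4 above-cutoff windows: a call
  s4 <- make_stream(1)
  s4$score[c(10, 14, 18, 22)] <- 0.9
  expect_gte(nrow(detect_calls(s4, cfg)), 1)
})

test_that("a recalled meal needs more than N positive windows in its horizon", {
  cfg <- call_config(n_windows = 3, horizon_minutes = 10)
  meals <- tibble::tibble(start_ts = ms(30), end_ts = ms(45))
  st <- make_stream(2)
  st$score[st$start_ts >= ms(31) & st$start_ts < ms(32)] <- 0.9  # 6 windows
  rec <- call_recall(st, meals, cfg)
  expect_true(rec$recalled)
  st2 <- make_stream(2)
  st2$score[c(200, 210, 220)] <- 0.9  # only 3 positives, outside anyway
  expect_false(call_recall(st2, meals, cfg)$recalled)
})

test_that("false-positive rate counts clustered regions once", {
  cfg <- call_config(n_windows = 3, horizon_minutes = 5)
  # all-zero negative stream: exactly 0 calls per hour
  expect_equal(false_positive_rate(make_stream(10), cfg, total_hours = 10), 0)

  # one isolated cluster of 5 above-cutoff windows in 2 h -> 0.5/h
  st <- make_stream(2)
  st$score[100:104] <- 0.9
  expect_equal(false_positive_rate(st, cfg, total_hours = 2), 0.5)

  expect_error(false_positive_rate(make_stream(1), cfg, total_hours = 0),
               class = "wristfork_usage_error")
})

test_that("recall and false positives are monotone non-increasing in the cutoff", {
  set.seed(32)
  cutoffs <- c(0.3, 0.4, 0.5, 0.6)
  # a realistic negative stream: near-zero scores with isolated excursion
  # clusters of varying peak height
  st <- make_stream(6)
  st$score <- runif(nrow(st), 0, 0.1)
  peaks <- c(0.35, 0.45, 0.55, 0.65, 0.8, 0.95)
  at <- round(seq(150, nrow(st) - 150, length.out = length(peaks)))
  for (i in seq_along(peaks)) {
    idx <- at[i] + 0:7
    st$score[idx] <- peaks[i] * runif(8, 0.9, 1)
  }
  meals <- tibble::tibble(start_ts = c(ms(30), ms(90), ms(200)),
                          end_ts = c(ms(45), ms(105), ms(215)))
  # meal-start blips of differing strength
  for (i in seq_len(nrow(meals))) {
    idx <- which(st$start_ts >= meals$start_ts[i])[1] + 0:5
    st$score[idx] <- c(0.95, 0.65, 0.45, 0.5, 0.35, 0.9)[i %% 6 + 1] *
      runif(6, 0.9, 1)
  }
  for (N in c(1, 3)) {
    rates <- sapply(cutoffs, function(co) {
      false_positive_rate(st, call_config(score_cutoff = co, n_windows = N),
                          total_hours = 6)
    })
    expect_true(all(diff(rates) <= 0))
    recs <- sapply(cutoffs, function(co) {
      mean(call_recall(st, meals,
                       call_config(score_cutoff = co, n_windows = N,
                                   horizon_minutes = 10))$recalled)
    })
    expect_true(all(diff(recs) <= 0))
  }
})
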