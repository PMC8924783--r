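# A fast config: short days so whole-day synthesis stays cheap. Condition
# parameters that matter to a test (meal counts, durations, rates) are left
# at their defaults there.
quick_config <- function(...) {
  gen_config(sampling_rate_hz = 2,
             day_start_window = c(8, 8.5), day_end_window = c(12, 12.5),
             meal_start_peaks = c(9, 10, 11), meal_start_weights = c(1, 1, 1) / 3,
             meal_duration_range = c(2, 25),
             ...)
}

test_that("sample spacing and counts follow the sampling rate", {
  cfg <- gen_config(sampling_rate_hz = 50,
                    day_start_window = c(8, 8), day_end_window = c(9, 9),
                    session_break_probability = 0, watch_off_probability = 0,
                    meal_start_peaks = c(8.3, 8.5, 8.7),
                    meal_duration_range = c(2, 10))
  sim <- simulate_day("P01", "2026-03-02", cfg, seed = 3)
  # one hour at 50 Hz
  expect_equal(nrow(sim$day), 180000)
  expect_equal(unique(round(diff(sim$day$ts), 6)), 20)
  expect_equal(unique(sim$day$sesid), 1L)
})

test_that("the same seed reproduces a day exactly", {
  cfg <- quick_config()
  a <- simulate_day("P01", "2026-03-02", cfg, seed = 42)
  b <- simulate_day("P01", "2026-03-02", cfg, seed = 42)
  expect_identical(a$day, b$day)
  expect_identical(a$truth, b$truth)
  c <- simulate_day("P01", "2026-03-02", cfg, seed = 43)
  expect_false(identical(a$day$gyro_x, c$day$gyro_x))
})

test_that("diary truth is exactly recoverable from the day's tags", {
  cfg <- quick_config()
  for (seed in 1:10) {
    sim <- simulate_day("P01", "2026-03-02", cfg, seed = seed)
    got <- extract_meals(sim$day)
    expect_equal(nrow(got), nrow(sim$truth))
    if (nrow(got) > 0) {
      expect_equal(got$start_ts, sim$truth$start_ts)
      expect_equal(got$end_ts, sim$truth$end_ts)
      expect_equal(got$retrospective, sim$truth$retrospective)
    }
  }
})

test_that("labels are consistent: tags only inside truth, tagTimely <= tag", {
  cfg <- quick_config()
  for (seed in 1:10) {
    sim <- simulate_day("P01", "2026-03-02", cfg, seed = seed)
    d <- sim$day
    expect_true(all(d$tagTimely <= d$tag))
    in_truth <- rep(FALSE, nrow(d))
    for (m in seq_len(nrow(sim$truth))) {
      in_truth <- in_truth |
        (d$ts >= sim$truth$start_ts[m] & d$ts < sim$truth$end_ts[m])
    }
    expect_true(all(d$tag[!in_truth] == 0))
    expect_true(all(d$tag[in_truth] == 1))
    validate_day(d)
  }
})

test_that("meals within a day never overlap and stay inside sessions", {
  cfg <- quick_config(session_break_probability = 1)
  for (seed in 1:10) {
    sim <- simulate_day("P01", "2026-03-02", cfg, seed = seed)
    tr <- sim$truth
    if (nrow(tr) > 1) {
      expect_true(all(tr$start_ts[-1] >= tr$end_ts[-nrow(tr)]))
    }
    for (m in seq_len(nrow(tr))) {
      rows <- sim$day$ts >= tr$start_ts[m] & sim$day$ts < tr$end_ts[m]
      expect_length(unique(sim$day$sesid[rows]), 1)
    }
  }
})

test_that("day-structure marginals match the configured distributions", {
  cfg <- gen_config()
  set.seed(99)
  plans <- replicate(150, simulate_day_plan(cfg), simplify = FALSE)

  counts <- vapply(plans, function(p) nrow(p$meals), numeric(1))
  expect_true(all(counts >= 1 & counts <= 7))
  expect_gt(mean(counts %in% 1:4), 0.85)

  durs <- unlist(lapply(plans, function(p) p$meals$dur_s)) / 60
  expect_equal(mean(durs < 20), 0.75, tolerance = 0.1)

  # wear spans: modal 8-15 h, starting 7-9 AM
  spans <- vapply(plans, function(p) (p$end_s - p$start_s) / 3600, numeric(1))
  expect_true(all(spans >= 10 & spans <= 14))
  starts <- vapply(plans, function(p) p$start_s / 3600, numeric(1))
  expect_true(all(starts >= 7 & starts <= 9))

  # start times cluster at the three configured peaks
  st_h <- unlist(lapply(plans, function(p) p$meals$start_s)) / 3600
  near_peak <- vapply(st_h, function(h) min(abs(h - cfg$meal_start_peaks)), numeric(1))
  expect_gt(mean(near_peak < 1.5), 0.8)
})

test_that("a fixed meal count yields that many non-overlapping truth meals", {
  cfg <- quick_config(meal_count_probs = c(`3` = 1))
  n <- vapply(1:100, function(s) {
    with_seed_ <- get("with_seed", envir = asNamespace("wristfork"))
    p <- with_seed_(s, simulate_day_plan(cfg))
    nrow(p$meals)
  }, numeric(1))
  expect_true(all(n == 3))
})

test_that("an energy threshold on gyroscope magnitude separates eating windows", {
  cfg <- gen_config(sampling_rate_hz = 4)
  scores <- c(); labels <- c()
  for (seed in 1:3) {
    sim <- simulate_day("P01", "2026-03-02", cfg, seed = seed)
    w <- make_windows(sim$day)
    keep <- w$label >= 0
    sig <- window_signals(sim$day, w[keep, ], channels = "gyro")
    scores <- c(scores, apply(sig, 1, function(m) mean(m^2)))
    labels <- c(labels, w$label[keep])
  }
  expect_gt(roc_auc(scores, labels), 0.7)
})

test_that("noncompliance injection produces the named artifacts", {
  cfg <- quick_config(session_break_probability = 0, watch_off_probability = 0)
  sim <- simulate_day("P01", "2026-03-02", cfg, seed = 5)
  day <- sim$day

  short <- inject_noncompliance(day, "short_day", cfg)
  expect_lt(day_duration_hours(short), 3)

  off <- inject_noncompliance(day, "watch_off", cfg, seed = 2)
  # direct segment scan: all six channels below baseline/100 for >= 10 min
  quiet <- rowSums(abs(as.matrix(off[c("accl_x", "accl_y", "accl_z",
                                       "gyro_x", "gyro_y", "gyro_z")])) <
                     cfg$baseline_noise_scale / 100) == 6
  r <- rle(quiet)
  rate <- cfg$sampling_rate_hz
  expect_true(any(r$values & r$lengths / rate >= 600))
  # the reporting detector sees it too
  seg <- detect_watch_off(off, threshold = cfg$baseline_noise_scale / 100)
  expect_gte(nrow(seg), 1)

  retro <- inject_noncompliance(day, "all_retro", cfg)
  m <- extract_meals(retro)
  expect_true(all(m$retrospective))

  none <- inject_noncompliance(day, "no_meals", cfg)
  expect_equal(sum(none$tag), 0)
  expect_equal(nrow(extract_meals(none)), 0)

  expect_error(inject_noncompliance(day, "bad_kind"),
               class = "wristfork_usage_error")
})

test_that("cohorts have the planned size and per-participant gestures differ", {
  cfg <- quick_config()
  co <- simulate_cohort(5, 2, cfg, seed = 7)
  expect_length(co$days, 10)
  expect_equal(nrow(co$plan), 10)
  g <- co$plan |> dplyr::distinct(participant_id, .keep_all = TRUE)
  amps <- vapply(g$gesture, function(x) x$amp_mult, numeric(1))
  expect_equal(length(unique(amps)), 5)

  co2 <- simulate_cohort(5, 2, cfg, seed = 7)
  expect_identical(co$days, co2$days)
})

test_that("invalid generator configs are rejected", {
  expect_error(gen_config(retro_fraction = 1.5), class = "wristfork_config_error")
  expect_error(gen_config(meal_count_probs = c(`8` = 1)),
               class = "wristfork_config_error")
  expect_error(gen_config(gesture_amplitude = -1))
  expect_error(gen_config(bite_interval_seconds = c(5, 3)),
               class = "wristfork_config_error")
})
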