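#' Generator configuration for synthetic free-living sensor days
#'
#' Defaults emulate the structure of free-living wrist recordings: days begin
#' between 7 and 9 AM and end between 7 and 9 PM (8-15 h of wear), hold 1-7
#' diary meals per day with most days having 1-4, meal durations are
#' log-normal with about 75% of meals shorter than 20 minutes, and meal start
#' times cluster at breakfast, lunch and dinner. During meals the dominant
#' wrist performs periodic hand-to-mouth gestures: smooth 1-2.5 s rotation
#' pulses repeating every few seconds, with correlated acceleration, riding on
#' band-limited baseline motion noise. Non-eating arm-swing bursts (confusers)
#' occur at a configurable hourly rate so the detection task is not trivially
#' separable by signal energy alone.
#'
#' @param sampling_rate_hz Samples per second per channel (default 50).
#' @param day_start_window,day_end_window Clock-hour ranges for the first and
#'   last sample of the day.
#' @param meal_count_probs Named probabilities for 1-7 meals per day.
#' @param meal_duration_meanlog,meal_duration_sdlog Log-normal parameters of
#'   meal duration in minutes; the defaults put ~75% of mass below 20 min.
#' @param meal_duration_range Truncation bounds (minutes) for meal durations.
#' @param meal_start_peaks,meal_start_sd,meal_start_weights Clock-hour modes,
#'   spread and weights of the meal start-time mixture.
#' @param bite_interval_seconds Range of seconds between successive bites.
#' @param bite_duration_seconds Range of a single bite pulse's duration.
#' @param gesture_amplitude Peak rotation rate of a bite pulse (rad/s).
#' @param baseline_noise_scale SD of baseline gyroscope noise (rad/s);
#'   accelerometer baseline noise is scaled down from it.
#' @param confuser_rate_per_hour Expected non-eating arm-swing bursts per hour.
#' @param confuser_amplitude Peak rotation rate of a confuser burst (rad/s).
#' @param session_break_probability Probability that a day contains recording
#'   breaks (1-3 gaps of at least 5 minutes, incrementing `sesid`).
#' @param retro_fraction Probability that a meal is tagged retrospectively.
#' @param watch_off_probability Probability of a near-zero (watch off wrist)
#'   segment in a day.
#' @param seed Optional integer seed making a single-day draw reproducible.
#' @return A `wf_gen_config` list.
#' @export
gen_config <- function(sampling_rate_hz = 50,
                       day_start_window = c(7, 9),
                       day_end_window = c(19, 21),
                       meal_count_probs = c(`1` = 0.18, `2` = 0.27, `3` = 0.27,
                                            `4` = 0.18, `5` = 0.06, `6` = 0.03,
                                            `7` = 0.01),
                       meal_duration_meanlog = log(12),
                       meal_duration_sdlog = 0.757,
                       meal_duration_range = c(2, 90),
                       meal_start_peaks = c(7.75, 12.25, 18.5),
                       meal_start_sd = 0.75,
                       meal_start_weights = c(0.3, 0.4, 0.3),
                       bite_interval_seconds = c(4, 7),
                       bite_duration_seconds = c(1, 2.5),
                       gesture_amplitude = 1.2,
                       baseline_noise_scale = 0.25,
                       confuser_rate_per_hour = 6,
                       confuser_amplitude = 1.5,
                       session_break_probability = 0.35,
                       retro_fraction = 0.1,
                       watch_off_probability = 0.05,
                       seed = NULL) {
  cfg <- list(
    sampling_rate_hz = sampling_rate_hz,
    day_start_window = day_start_window,
    day_end_window = day_end_window,
    meal_count_probs = meal_count_probs,
    meal_duration_meanlog = meal_duration_meanlog,
    meal_duration_sdlog = meal_duration_sdlog,
    meal_duration_range = meal_duration_range,
    meal_start_peaks = meal_start_peaks,
    meal_start_sd = meal_start_sd,
    meal_start_weights = meal_start_weights,
    bite_interval_seconds = bite_interval_seconds,
    bite_duration_seconds = bite_duration_seconds,
    gesture_amplitude = gesture_amplitude,
    baseline_noise_scale = baseline_noise_scale,
    confuser_rate_per_hour = confuser_rate_per_hour,
    confuser_amplitude = confuser_amplitude,
    session_break_probability = session_break_probability,
    retro_fraction = retro_fraction,
    watch_off_probability = watch_off_probability,
    seed = seed
  )
  class(cfg) <- "wf_gen_config"
  validate_gen_config(cfg)
}

validate_gen_config <- function(cfg) {
  stopifnot_scalar_number(cfg$sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  for (p in c("session_break_probability", "retro_fraction", "watch_off_probability")) {
    if (!is_prob(cfg[[p]])) {
      abort(sprintf("configuration error: `%s` must be a probability in [0, 1].", p),
            class = "wristfork_config_error")
    }
  }
  probs <- cfg$meal_count_probs
  if (is.null(names(probs)) ||
      !all(names(probs) %in% as.character(1:7)) ||
      any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    abort("configuration error: `meal_count_probs` must be probabilities named within 1..7 summing to 1.",
          class = "wristfork_config_error")
  }
  for (rng in c("day_start_window", "day_end_window", "meal_duration_range",
                "bite_interval_seconds", "bite_duration_seconds")) {
    v <- cfg[[rng]]
    if (!is.numeric(v) || length(v) != 2 || any(!is.finite(v)) || v[1] > v[2] || v[1] <= 0) {
      abort(sprintf("configuration error: `%s` must be a positive increasing range.", rng),
            class = "wristfork_config_error")
    }
  }
  for (pos in c("gesture_amplitude", "baseline_noise_scale", "confuser_amplitude",
                "meal_start_sd")) {
    stopifnot_scalar_number(cfg[[pos]], pos, positive = TRUE)
  }
  invisible(cfg)
}

default_gesture <- function() {
  list(
    gyro_mix = c(1, 0.35, 0.2) / sqrt(sum(c(1, 0.35, 0.2)^2)),
    accl_mix = c(0.5, 1, 0.3) / sqrt(sum(c(0.5, 1, 0.3)^2)),
    amp_mult = 1,
    interval_mult = 1
  )
}

# Per-participant jitter of gesture kinematics so individuals differ
# (what personal fine-tuning has to adapt to).
jitter_gesture <- function(spread = 1) {
  g <- default_gesture()
  jmix <- function(m) {
    m <- m + rnorm(3, sd = 0.15 * spread)
    m / sqrt(sum(m^2))
  }
  g$gyro_mix <- jmix(g$gyro_mix)
  g$accl_mix <- jmix(g$accl_mix)
  g$amp_mult <- exp(rnorm(1, sd = 0.12 * spread))
  g$interval_mult <- exp(rnorm(1, sd = 0.10 * spread))
  g
}

#' Draw the structural layout of one synthetic day
#'
#' Samples the wear interval, session gaps, meals (with retrospective flags
#' and utensils) and an optional watch-off segment, without synthesizing any
#' signals — the cheap structural half of [simulate_day()]. Useful for
#' studying the generator's marginal distributions (meal counts, durations,
#' start times) over many days, and for cleaning decisions that only need
#' the layout. Times are seconds since midnight. Uses the current RNG
#' stream.
#'
#' @param config A [gen_config()].
#' @return List with `start_s`, `end_s`, `meals` (tibble: `start_s`,
#'   `dur_s`, `retro`, `utensils`), `gaps`, `watch_off`.
#' @export
simulate_day_plan <- function(config = gen_config()) {
  validate_gen_config(config)
  start_s <- runif(1, config$day_start_window[1], config$day_start_window[2]) * 3600
  end_s <- runif(1, config$day_end_window[1], config$day_end_window[2]) * 3600

  n_meals <- as.integer(sample(names(config$meal_count_probs), 1,
                               prob = config$meal_count_probs))
  meals <- NULL
  placed <- 0L
  tries <- 0L
  starts <- c(); durs <- c()
  while (placed < n_meals && tries < 500L) {
    tries <- tries + 1L
    peak <- sample(seq_along(config$meal_start_peaks), 1,
                   prob = config$meal_start_weights)
    st <- rnorm(1, config$meal_start_peaks[peak], config$meal_start_sd) * 3600
    dur <- rlnorm(1, config$meal_duration_meanlog, config$meal_duration_sdlog)
    dur <- min(max(dur, config$meal_duration_range[1]), config$meal_duration_range[2]) * 60
    if (st < start_s + 120 || st + dur > end_s - 120) next
    # 10-min spacing between meals keeps truth intervals distinct.
    if (placed > 0 && any(st < starts + durs + 600 & st + dur + 600 > starts)) next
    starts <- c(starts, st); durs <- c(durs, dur); placed <- placed + 1L
  }
  ord <- order(starts)
  starts <- starts[ord]; durs <- durs[ord]
  n_meals <- length(starts)
  meals <- tibble::tibble(
    start_s = starts, dur_s = durs,
    retro = rbinom(n_meals, 1, config$retro_fraction) == 1,
    utensils = purrr::map_chr(seq_len(max(n_meals, 0)), function(i) {
      paste(sort(sample(utensil_cols(), sample(1:2, 1))), collapse = ",")
    })
  )

  free_interval <- function(min_len, avoid, lo, hi, tries = 200L) {
    # one interval of length >= min_len avoiding all rows of `avoid`
    for (t in seq_len(tries)) {
      len <- runif(1, min_len, min_len * 4)
      st <- runif(1, lo, hi - len)
      if (nrow(avoid) == 0 ||
          all(st + len <= avoid$start | st >= avoid$end)) {
        return(c(st, st + len))
      }
    }
    NULL
  }

  avoid <- tibble::tibble(start = meals$start_s - 60, end = meals$start_s + meals$dur_s + 60)
  gaps <- tibble::tibble(start_s = double(), end_s = double())
  if (runif(1) < config$session_break_probability) {
    n_gaps <- sample(1:3, 1)
    for (g in seq_len(n_gaps)) {
      iv <- free_interval(300, avoid, start_s + 600, end_s - 600)
      if (is.null(iv)) next
      gaps <- dplyr::bind_rows(gaps, tibble::tibble(start_s = iv[1], end_s = iv[2]))
      avoid <- dplyr::bind_rows(avoid, tibble::tibble(start = iv[1], end = iv[2]))
    }
    gaps <- dplyr::arrange(gaps, .data$start_s)
  }

  watch_off <- tibble::tibble(start_s = double(), end_s = double())
  if (runif(1) < config$watch_off_probability) {
    iv <- free_interval(600, avoid, start_s + 600, end_s - 600)
    if (!is.null(iv)) watch_off <- tibble::tibble(start_s = iv[1], end_s = min(iv[2], iv[1] + 2400))
  }

  list(start_s = start_s, end_s = end_s, meals = meals, gaps = gaps,
       watch_off = watch_off)
}

# AR(1)-filtered Gaussian noise with unit variance, time constant tau seconds.
ar_noise <- function(n, rate, tau) {
  a <- exp(-1 / (rate * tau))
  e <- rnorm(n)
  x <- stats::filter(e, a, method = "recursive")
  as.numeric(x) / sqrt(1 / (1 - a^2))
}

# indices of the sorted time grid falling in [a, b)
idx_range <- function(tsec, a, b) {
  i0 <- findInterval(a - 1e-7, tsec) + 1L
  i1 <- findInterval(b - 1e-7, tsec)
  if (i1 < i0) integer(0) else i0:i1
}

# Add one smooth raised-cosine pulse to 3 channels with a direction mix.
add_pulse <- function(mat, cols, tsec, t0, dur, amp, mix) {
  idx <- idx_range(tsec, t0, t0 + dur)
  if (length(idx) == 0) return(mat)
  u <- (tsec[idx] - t0) / dur
  pulse <- amp * 0.5 * (1 - cos(2 * pi * u))
  for (j in 1:3) mat[idx, cols[j]] <- mat[idx, cols[j]] + pulse * mix[j]
  mat
}

#' Simulate one labeled participant-day of wrist sensor data
#'
#' Draws a day layout (wear interval, sessions, meals) and synthesizes the
#' six motion channels at `config$sampling_rate_hz`: baseline band-limited
#' noise, a per-day gravity orientation on the accelerometer, periodic bite
#' pulses inside meals, and sparse non-eating arm-swing bursts outside them.
#' Diary labels are set per the layout: `tag = 1` inside meals, `tagTimely`
#' for timely meals, `tagRetro` for retrospectively logged ones. Acceleration
#' is in g, rotation rate in rad/s.
#'
#' @param participant_id,date Identity of the day.
#' @param config A [gen_config()].
#' @param gesture Per-participant gesture parameters (default population
#'   values; see [simulate_cohort()] for jittered individuals).
#' @param seed Optional seed (defaults to `config$seed`); the same seed and
#'   config reproduce the day exactly.
#' @return A list with `day` (sensor-day tibble) and `truth` (meal tibble as
#'   in [extract_meals()]).
#' @export
simulate_day <- function(participant_id, date, config = gen_config(),
                         gesture = NULL, seed = config$seed) {
  with_seed(seed, {
    gesture <- gesture %||% default_gesture()
    plan <- simulate_day_plan(config)
    rate <- config$sampling_rate_hz
    period <- 1 / rate

    # sample grid over the half-open wear interval [start, end)
    k0 <- ceiling(plan$start_s * rate)
    k1 <- ceiling(plan$end_s * rate) - 1
    tsec <- (k0:k1) / rate
    in_gap <- rep(FALSE, length(tsec))
    for (g in seq_len(nrow(plan$gaps))) {
      in_gap <- in_gap | (tsec >= plan$gaps$start_s[g] & tsec < plan$gaps$end_s[g])
    }
    tsec <- tsec[!in_gap]
    n <- length(tsec)
    # session index increments after each recording gap
    sesid <- 1L + findInterval(tsec, sort(plan$gaps$end_s))

    sig <- matrix(0, n, 6)
    colnames(sig) <- motion_cols()
    g0 <- rnorm(3); g0 <- g0 / sqrt(sum(g0^2))
    for (j in 1:3) {
      sig[, j] <- g0[j] + 0.05 * ar_noise(n, rate, 120) +
        0.4 * config$baseline_noise_scale * ar_noise(n, rate, 0.4)
      sig[, j + 3] <- config$baseline_noise_scale * ar_noise(n, rate, 0.3)
    }

    # snap meal boundaries to the sample grid so diary truth is exact
    meals <- plan$meals
    if (nrow(meals) > 0) {
      meals$start_s <- round(meals$start_s * rate) / rate
      meals$dur_s <- pmax(round(meals$dur_s * rate) / rate, 2 * period)
    }

    # bite pulses inside meals
    for (m in seq_len(nrow(meals))) {
      t0 <- meals$start_s[m]; t1 <- t0 + meals$dur_s[m]
      tt <- t0 + runif(1, 0, 2)
      while (tt < t1 - 0.5) {
        dur <- runif(1, config$bite_duration_seconds[1], config$bite_duration_seconds[2])
        amp <- config$gesture_amplitude * gesture$amp_mult * runif(1, 0.7, 1.3)
        sig <- add_pulse(sig, 4:6, tsec, tt, dur, amp, gesture$gyro_mix)
        sig <- add_pulse(sig, 1:3, tsec, tt, dur, amp * 0.12, gesture$accl_mix)
        tt <- tt + gesture$interval_mult *
          runif(1, config$bite_interval_seconds[1], config$bite_interval_seconds[2])
      }
    }

    # non-eating confusers: short arm-swing bursts plus sustained activity
    # bouts (walking-like oscillation lasting minutes), both outside meals
    active_h <- (plan$end_s - plan$start_s) / 3600
    in_meal_t <- function(t) {
      nrow(meals) > 0 && any(t >= meals$start_s - 30 & t <= meals$start_s + meals$dur_s + 30)
    }
    add_osc <- function(sig, tt, dur, amp, f) {
      idx <- idx_range(tsec, tt, tt + dur)
      if (length(idx) == 0) return(sig)
      u <- (tsec[idx] - tt) / dur
      env <- sin(pi * u)
      mix <- rnorm(3); mix <- mix / sqrt(sum(mix^2))
      osc <- amp * env * sin(2 * pi * f * (tsec[idx] - tt))
      for (j in 1:3) {
        sig[idx, 3 + j] <- sig[idx, 3 + j] + osc * mix[j]
        sig[idx, j] <- sig[idx, j] + 0.1 * osc * mix[j]
      }
      sig
    }
    n_burst <- rpois(1, config$confuser_rate_per_hour * active_h)
    for (cid in seq_len(n_burst)) {
      tt <- runif(1, plan$start_s, plan$end_s - 20)
      if (in_meal_t(tt)) next
      sig <- add_osc(sig, tt, runif(1, 5, 20), config$confuser_amplitude * runif(1, 0.6, 1.2),
                     runif(1, 0.8, 1.3))
    }
    n_bout <- rpois(1, 0.4 * active_h)
    for (cid in seq_len(n_bout)) {
      tt <- runif(1, plan$start_s, plan$end_s - 600)
      dur <- runif(1, 120, 480)
      if (in_meal_t(tt) || in_meal_t(tt + dur)) next
      sig <- add_osc(sig, tt, dur, config$confuser_amplitude * runif(1, 0.4, 0.7),
                     runif(1, 0.9, 1.4))
    }

    # watch-off: all six channels collapse to near zero
    for (w in seq_len(nrow(plan$watch_off))) {
      idx <- idx_range(tsec, plan$watch_off$start_s[w], plan$watch_off$end_s[w])
      sig[idx, ] <- matrix(rnorm(length(idx) * 6, sd = config$baseline_noise_scale / 500),
                           length(idx), 6)
    }

    # diary labels
    tag <- integer(n); timely <- integer(n); retro <- rep(NA_real_, n)
    ut <- matrix(0L, n, 6); colnames(ut) <- utensil_cols()
    for (m in seq_len(nrow(meals))) {
      idx <- idx_range(tsec, meals$start_s[m], meals$start_s[m] + meals$dur_s[m])
      tag[idx] <- 1L
      if (meals$retro[m]) retro[idx] <- 1 else timely[idx] <- 1L
      for (u in strsplit(meals$utensils[m], ",")[[1]]) ut[idx, u] <- 1L
    }

    date <- as.Date(date)
    epoch_ms <- as.numeric(as.POSIXct(paste(date, "00:00:00"), tz = "UTC")) * 1000
    samples <- tibble::tibble(
      ts = epoch_ms + tsec * 1000,
      tod = tsec,
      sesid = as.integer(sesid)
    )
    samples <- dplyr::bind_cols(samples, tibble::as_tibble(sig),
                                tibble::as_tibble(ut))
    samples$tag <- tag
    samples$tagTimely <- timely
    samples$tagRetro <- retro

    day <- sensor_day(samples, participant_id, date, validate = FALSE)
    truth <- if (nrow(meals) == 0) {
      extract_meals(day[0, ])
    } else {
      tibble::tibble(
        participant_id = as.character(participant_id), date = date,
        start_ts = epoch_ms + meals$start_s * 1000,
        end_ts = epoch_ms + (meals$start_s + meals$dur_s) * 1000,
        retrospective = meals$retro,
        utensils = meals$utensils
      )
    }
    list(day = day, truth = truth)
  })
}

#' Plan a synthetic cohort
#'
#' Draws participant identities, per-participant gesture jitters and one
#' reproducible seed per participant-day, without synthesizing any signals.
#' Feed rows to [simulate_day()] to materialize days lazily.
#'
#' @param n_participants,days_per_participant Cohort dimensions.
#' @param config A [gen_config()].
#' @param seed Master seed.
#' @param gesture_spread Scale of between-participant gesture jitter.
#' @param start_date First recording date.
#' @return Tibble with `participant_id`, `date`, `day_seed`, `gesture`
#'   (list-column).
#' @export
cohort_plan <- function(n_participants, days_per_participant,
                        config = gen_config(), seed = 1,
                        gesture_spread = 1,
                        start_date = as.Date("2026-03-02")) {
  if (n_participants < 1) abort("`n_participants` must be >= 1.")
  with_seed(seed, {
    ids <- sprintf("P%02d", seq_len(n_participants))
    gestures <- purrr::map(ids, ~ jitter_gesture(gesture_spread))
    tidyr::expand_grid(
      participant_id = ids,
      day_index = seq_len(days_per_participant)
    ) |>
      dplyr::mutate(
        date = start_date + .data$day_index - 1L,
        day_seed = derive_seed(seed, dplyr::row_number()),
        gesture = gestures[match(.data$participant_id, ids)]
      ) |>
      dplyr::select("participant_id", "date", "day_seed", "gesture")
  })
}

#' Simulate a full synthetic cohort
#'
#' Materializes every planned participant-day. Each participant carries
#' jittered gesture kinematics so individuals differ (the premise of personal
#' fine-tuning).
#'
#' @inheritParams cohort_plan
#' @return A `wf_cohort`: list with `plan`, `days` (named list of sensor-day
#'   tibbles, `"<participant>_<date>"`), and `truth` (all meals).
#' @export
simulate_cohort <- function(n_participants, days_per_participant,
                            config = gen_config(), seed = 1,
                            gesture_spread = 1) {
  plan <- cohort_plan(n_participants, days_per_participant, config, seed,
                      gesture_spread)
  days <- list(); truths <- list()
  for (i in seq_len(nrow(plan))) {
    sim <- simulate_day(plan$participant_id[i], plan$date[i], config,
                        gesture = plan$gesture[[i]], seed = plan$day_seed[i])
    key <- sprintf("%s_%s", plan$participant_id[i], plan$date[i])
    days[[key]] <- sim$day
    truths[[key]] <- sim$truth
  }
  structure(
    list(plan = plan, days = days, truth = dplyr::bind_rows(truths)),
    class = "wf_cohort"
  )
}

#' Inject a noncompliance artifact into a sensor day
#'
#' Produces the data-quality failure modes the cleaning stage must catch:
#' `watch_off` (a contiguous >= 10 min segment with all six motion channels
#' near zero), `short_day` (total recorded duration under 3 h), `all_retro`
#' (every meal flagged retrospective) and `no_meals` (all diary tags
#' stripped).
#'
#' @param day A sensor-day tibble.
#' @param kind One of `"watch_off"`, `"short_day"`, `"all_retro"`,
#'   `"no_meals"`.
#' @param config The generator config (supplies the baseline noise scale for
#'   `watch_off`).
#' @param seed Optional seed.
#' @return The modified sensor-day tibble.
#' @export
inject_noncompliance <- function(day, kind, config = gen_config(), seed = NULL) {
  kinds <- c("watch_off", "short_day", "all_retro", "no_meals")
  if (!is.character(kind) || length(kind) != 1 || !kind %in% kinds) {
    abort(sprintf("unknown noncompliance kind; expected one of %s",
                  paste(kinds, collapse = ", ")), class = "wristfork_usage_error")
  }
  with_seed(seed, {
    switch(kind,
      watch_off = {
        dur_ms <- runif(1, 12, 30) * 60000
        t0 <- runif(1, day$ts[1], max(day$ts[1], day$ts[nrow(day)] - dur_ms))
        idx <- which(day$ts >= t0 & day$ts < t0 + dur_ms)
        if (length(idx) < 2) idx <- seq_len(min(nrow(day), 100L))
        for (col in motion_cols()) {
          day[[col]][idx] <- rnorm(length(idx), sd = config$baseline_noise_scale / 500)
        }
        day
      },
      short_day = {
        keep <- day$ts < day$ts[1] + 2.5 * 3600 * 1000
        day[keep, ]
      },
      all_retro = {
        day$tagRetro[day$tag == 1] <- 1
        day$tagTimely <- 0L
        day
      },
      no_meals = {
        day$tag <- 0L
        day$tagTimely <- 0L
        day$tagRetro <- NA_real_
        for (col in utensil_cols()) day[[col]] <- 0L
        day
      }
    )
  })
}
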