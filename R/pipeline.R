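#' Experiment configuration
#'
#' Bundles every stage's settings for [run_experiment()]. The defaults
#' describe the reference synthetic study: 14 participants, 10 days each,
#' subject-wise evaluation with 3 held-out test participants, 2 validation
#' participants per ensemble member and 5 members, gyroscope-only input with
#' per-window centering and magnitude-scaling augmentation.
#'
#' To keep a full run tractable on one CPU the pipeline works on a
#' subsample of windows per day (`train_pos_per_day`/`train_neg_per_day`
#' for training, `eval_pos_per_day`/`eval_neg_per_day` for window-level
#' evaluation) and evaluates the hourly false-positive rate on
#' `fp_hours` sampled negative hours; meal-level scoring always uses every
#' window inside the scored regions.
#'
#' @param generator A [gen_config()].
#' @param n_participants,days_per_participant Cohort size.
#' @param channels `"gyro"`, `"accl"` or `"both"`.
#' @param window_seconds,step_seconds,min_meal_seconds Windowing settings.
#' @param transforms A [transform_config()].
#' @param training A [train_config()].
#' @param call A [call_config()].
#' @param mode `"cross_validation"`, `"leave_one_subject_out"` or
#'   `"personalized"`.
#' @param n_folds Cross-validation folds (test subjects are redrawn per
#'   fold).
#' @param n_test,n_val,n_members Split plan dimensions.
#' @param train_pos_per_day,train_neg_per_day,eval_pos_per_day,eval_neg_per_day
#'   Per-day window subsample caps.
#' @param fp_hours Negative hours sampled for the false-positive rate.
#' @param gesture_spread Between-participant gesture variability.
#' @param master_seed One integer seeding every stage (all stage seeds are
#'   derived from it, so reruns reproduce the report exactly).
#' @return A `wf_experiment_config` list.
#' @export
experiment_config <- function(generator = gen_config(),
                              n_participants = 14, days_per_participant = 10,
                              channels = c("gyro", "accl", "both"),
                              window_seconds = 300, step_seconds = 20,
                              min_meal_seconds = 180,
                              transforms = transform_config(),
                              training = train_config(),
                              call = call_config(horizon_minutes = 10),
                              mode = c("cross_validation",
                                       "leave_one_subject_out",
                                       "personalized"),
                              n_folds = 1, n_test = 3, n_val = 2,
                              n_members = 5,
                              train_pos_per_day = 10, train_neg_per_day = 15,
                              eval_pos_per_day = 30, eval_neg_per_day = 60,
                              fp_hours = 10, gesture_spread = 1,
                              master_seed = 1) {
  cfg <- list(
    generator = generator, n_participants = n_participants,
    days_per_participant = days_per_participant,
    channels = match.arg(channels),
    window_seconds = window_seconds, step_seconds = step_seconds,
    min_meal_seconds = min_meal_seconds,
    transforms = transforms, training = training, call = call,
    mode = match.arg(mode), n_folds = n_folds, n_test = n_test,
    n_val = n_val, n_members = n_members,
    train_pos_per_day = train_pos_per_day,
    train_neg_per_day = train_neg_per_day,
    eval_pos_per_day = eval_pos_per_day,
    eval_neg_per_day = eval_neg_per_day,
    fp_hours = fp_hours, gesture_spread = gesture_spread,
    master_seed = master_seed
  )
  class(cfg) <- "wf_experiment_config"
  cfg
}

n_channels_of <- function(channels) if (channels == "both") 3L * 2L else 3L

# stack a list of (n_i, len, ch) arrays along the first dimension
bind_signal_arrays <- function(lst) {
  lst <- lst[vapply(lst, function(a) !is.null(a) && dim(a)[1] > 0, logical(1))]
  if (length(lst) == 0) return(NULL)
  d <- dim(lst[[1]])
  n_tot <- sum(vapply(lst, function(a) dim(a)[1], numeric(1)))
  out <- array(0, dim = c(n_tot, d[2], d[3]))
  at <- 0L
  for (a in lst) {
    n <- dim(a)[1]
    if (n > 0) out[at + seq_len(n), , ] <- a
    at <- at + n
  }
  out
}

# day-plan-level cleaning summary (used before any signal is synthesized)
plan_cleaning <- function(day_plans, retro_threshold = 0.5, min_day_hours = 3) {
  info <- purrr::map_dfr(day_plans, function(p) {
    gap_s <- if (nrow(p$plan$gaps) > 0) sum(p$plan$gaps$end_s - p$plan$gaps$start_s) else 0
    tibble::tibble(
      participant_id = p$participant_id, date = p$date,
      hours = (p$plan$end_s - p$plan$start_s - gap_s) / 3600,
      n_meals = nrow(p$plan$meals),
      n_retro = sum(p$plan$meals$retro)
    )
  })
  by_part <- info |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(retro_frac = ifelse(sum(.data$n_meals) > 0,
                                         sum(.data$n_retro) / sum(.data$n_meals), 0),
                     .groups = "drop")
  bad_part <- by_part$participant_id[by_part$retro_frac > retro_threshold]
  info$retained <- !(info$participant_id %in% bad_part) &
    info$hours >= min_day_hours & info$n_meals > 0
  info
}

# windows whose midpoint falls inside [a, b)
rows_in_region <- function(win, a, b) {
  mid <- (win$start_ts + win$end_ts) / 2
  which(mid >= a & mid < b)
}

# matched negative regions for a set of meals on one day
draw_negative_regions <- function(meals, lo, hi, buffer_ms, tries = 200) {
  out <- list()
  for (i in seq_len(nrow(meals))) {
    len <- meals$end_ts[i] - meals$start_ts[i]
    for (t in seq_len(tries)) {
      a <- runif(1, lo, hi - len)
      b <- a + len
      if (any(a < meals$end_ts + buffer_ms & b > meals$start_ts - buffer_ms)) next
      out[[length(out) + 1]] <- tibble::tibble(start_ts = a, end_ts = b)
      break
    }
  }
  dplyr::bind_rows(out)
}

# fixed-stride window grid over a day's sample index range
stride_windows <- function(day, rate, window_seconds, stride_seconds,
                           from_ts = NULL, to_ts = NULL) {
  n_win <- as.integer(round(window_seconds * rate))
  stride <- max(1L, as.integer(round(stride_seconds * rate)))
  lo <- if (is.null(from_ts)) 1L else findInterval(from_ts - 1e-6, day$ts) + 1L
  hi <- if (is.null(to_ts)) nrow(day) else findInterval(to_ts - 1e-6, day$ts)
  last_start <- hi - n_win + 1L
  if (last_start < lo) return(NULL)
  starts <- seq.int(lo, last_start, by = stride)
  tibble::tibble(start_idx = starts, end_idx = starts + n_win - 1L,
                 start_ts = day$ts[starts], end_ts = day$ts[starts + n_win - 1L] +
                   1000 / rate)
}

extract_idx <- function(day, idx_tbl, channels) {
  cols <- switch(channels,
    gyro = c("gyro_x", "gyro_y", "gyro_z"),
    accl = c("accl_x", "accl_y", "accl_z"),
    both = motion_cols()
  )
  sig <- as.matrix(day[cols])
  n <- nrow(idx_tbl)
  if (n == 0) return(NULL)
  len <- idx_tbl$end_idx[1] - idx_tbl$start_idx[1] + 1L
  out <- array(0, dim = c(n, len, length(cols)))
  for (i in seq_len(n)) out[i, , ] <- sig[idx_tbl$start_idx[i]:idx_tbl$end_idx[i], ]
  out
}

# Generate one day and pull out exactly the windows the fold needs.
harvest_day <- function(prow, role, cfg, with_fp_hour, seed) {
  sim <- simulate_day(prow$participant_id, prow$date, cfg$generator,
                      gesture = prow$gesture[[1]], seed = prow$day_seed)
  day <- sim$day
  truth <- sim$truth
  rate <- cfg$generator$sampling_rate_hz
  win <- make_windows(day, cfg$window_seconds, cfg$step_seconds,
                      cfg$min_meal_seconds)
  out <- list(participant_id = prow$participant_id, date = prow$date,
              truth = truth)

  with_seed(seed, {
    if (role %in% c("train", "val")) {
      usable <- which(win$label >= 0)
      pos <- usable[win$label[usable] == 1L]
      neg <- usable[win$label[usable] == 0L]
      cap <- c(cfg$train_pos_per_day, cfg$train_neg_per_day)
      keep <- c(
        if (length(pos) > cap[1]) sample(pos, cap[1]) else pos,
        if (length(neg) > cap[2]) sample(neg, cap[2]) else neg
      )
      kw <- win[sort(keep), ]
      out$fit_meta <- tibble::as_tibble(kw)[c("participant_id", "date",
                                              "start_ts", "end_ts", "label")]
      out$fit_signals <- extract_idx(day, kw, cfg$channels)
    }

    if (role == "test") {
      usable <- which(win$label >= 0)
      pos <- usable[win$label[usable] == 1L]
      neg <- usable[win$label[usable] == 0L]
      keep <- c(
        if (length(pos) > cfg$eval_pos_per_day) sample(pos, cfg$eval_pos_per_day) else pos,
        if (length(neg) > cfg$eval_neg_per_day) sample(neg, cfg$eval_neg_per_day) else neg
      )
      kw <- win[sort(keep), ]
      out$eval_meta <- tibble::as_tibble(kw)[c("participant_id", "date",
                                               "start_ts", "end_ts", "label")]
      out$eval_signals <- extract_idx(day, kw, cfg$channels)

      # meal-level aggregation material: usable (non-retro, long-enough) meals
      meals <- truth[!truth$retrospective &
                       (truth$end_ts - truth$start_ts) / 1000 >= cfg$min_meal_seconds, ]
      if (nrow(meals) > 0) {
        lo <- day$ts[1]; hi <- day$ts[nrow(day)]
        negs <- draw_negative_regions(meals, lo, hi, buffer_ms = 10 * 60000)
        regions <- dplyr::bind_rows(
          dplyr::transmute(meals, .data$start_ts, .data$end_ts, is_meal = TRUE),
          dplyr::mutate(negs, is_meal = FALSE)
        )
        if (sum(regions$is_meal) == nrow(negs)) {
          rows <- purrr::map(seq_len(nrow(regions)), function(i) {
            rows_in_region(win, regions$start_ts[i], regions$end_ts[i])
          })
          used <- sort(unique(unlist(rows)))
          if (length(used) > 0) {
            kw <- win[used, ]
            out$region_meta <- regions
            out$region_rows <- purrr::map(rows, ~ match(.x, used))
            out$region_signals <- extract_idx(day, kw, cfg$channels)
          }
        }

        # call-recall material: 10-s-stride windows in the first horizon
        # after each meal start
        horizon_ms <- cfg$call$horizon_minutes * 60000
        rec <- purrr::map(seq_len(nrow(meals)), function(i) {
          stride_windows(day, rate, cfg$window_seconds, cfg$call$step_seconds,
                         from_ts = meals$start_ts[i],
                         to_ts = meals$start_ts[i] + horizon_ms +
                           cfg$window_seconds * 1000)
        })
        keep_meal <- !vapply(rec, is.null, logical(1))
        if (any(keep_meal)) {
          rec_tbl <- dplyr::bind_rows(rec[keep_meal], .id = "meal")
          out$recall_meals <- meals[keep_meal, ]
          out$recall_meta <- rec_tbl
          out$recall_signals <- extract_idx(day, rec_tbl, cfg$channels)
        }

        # one negative hour for the false-positive rate, when requested
        if (with_fp_hour) {
          lo_h <- day$ts[1]; hi_h <- day$ts[nrow(day)]
          for (t in 1:50) {
            a <- runif(1, lo_h, hi_h - 3.6e6)
            b <- a + 3.6e6
            clash <- nrow(truth) > 0 &&
              any(a < truth$end_ts + 6e5 & b > truth$start_ts - 6e5)
            if (clash) next
            fp_tbl <- stride_windows(day, rate, cfg$window_seconds,
                                     cfg$call$step_seconds, from_ts = a,
                                     to_ts = b + cfg$window_seconds * 1000)
            if (!is.null(fp_tbl)) {
              out$fp_meta <- fp_tbl
              out$fp_signals <- extract_idx(day, fp_tbl, cfg$channels)
            }
            break
          }
        }
      }
    }
  })
  out
}

#' Run a full detection experiment on synthetic data
#'
#' Orchestrates the pipeline end to end: plan the cohort, apply the
#' cleaning rules, split subjects, simulate each day and harvest its
#' windows, train the ensemble (with on-the-fly augmentation and
#' oversampling), then evaluate held-out subjects at the window level, at
#' the meal level against length-matched negative regions, and at the alarm
#' level (per-meal call recall within the horizon and false-positive calls
#' per negative hour). Everything derives from `cfg$master_seed`, so a
#' rerun reproduces the report bit for bit.
#'
#' @param cfg An [experiment_config()].
#' @param progress Print per-stage progress messages.
#' @return A `wf_report`: list with `window_metrics`, `member_aucs`,
#'   `region_scores`, `meal_metrics`, `recall`, `fp_rate`, `cleaning`,
#'   `folds`, `config`.
#' @export
run_experiment <- function(cfg = experiment_config(), progress = interactive()) {
  say <- function(...) if (progress) message(sprintf(...))
  master <- cfg$master_seed

  plan <- cohort_plan(cfg$n_participants, cfg$days_per_participant,
                      cfg$generator, seed = derive_seed(master, 1),
                      gesture_spread = cfg$gesture_spread)

  # structural pass: day layouts only, for cleaning decisions
  day_plans <- purrr::map(seq_len(nrow(plan)), function(i) {
    list(participant_id = plan$participant_id[i], date = plan$date[i],
         plan = with_seed(plan$day_seed[i], simulate_day_plan(cfg$generator)))
  })
  cleaning <- plan_cleaning(day_plans)
  retained <- cleaning[cleaning$retained, ]
  participants <- sort(unique(retained$participant_id))
  say("cohort: %d participants, %d/%d days retained after cleaning",
      length(participants), nrow(retained), nrow(plan))

  folds <- switch(cfg$mode,
    cross_validation = {
      purrr::map(seq_len(cfg$n_folds), function(f) {
        split_plan(participants, cfg$n_test, cfg$n_val, cfg$n_members,
                   seed = derive_seed(master, 10 + f))
      })
    },
    leave_one_subject_out = {
      purrr::map(seq_along(participants), function(f) {
        split_plan(participants, n_test = 1, cfg$n_val, cfg$n_members,
                   test_ids = participants[f],
                   seed = derive_seed(master, 10 + f))
      })
    },
    personalized = abort(
      "use `personalization_experiment()` for the fine-tuning protocol.",
      class = "wristfork_usage_error")
  )

  fold_reports <- purrr::map(seq_along(folds), function(f) {
    fplan <- folds[[f]]
    say("fold %d/%d: test = %s", f, length(folds),
        paste(fplan$test_ids, collapse = ", "))
    run_fold(cfg, plan, retained, fplan, fold_seed = derive_seed(master, 1000 + f),
             say = say)
  })

  report <- structure(list(
    window_metrics = purrr::map_dfr(fold_reports, "window_metrics", .id = "fold"),
    member_aucs = purrr::map_dfr(fold_reports, "member_aucs", .id = "fold"),
    region_scores = purrr::map_dfr(fold_reports, "region_scores", .id = "fold"),
    meal_metrics = purrr::map_dfr(fold_reports, "meal_metrics", .id = "fold"),
    recall = purrr::map_dfr(fold_reports, "recall", .id = "fold"),
    fp_rate = purrr::map_dfr(fold_reports, "fp_rate", .id = "fold"),
    scored_eval = purrr::map_dfr(fold_reports, "scored_eval", .id = "fold"),
    cleaning = cleaning,
    folds = folds,
    config = cfg
  ), class = "wf_report")
  report
}

run_fold <- function(cfg, plan, retained, fplan, fold_seed, say = function(...) NULL) {
  retained$key <- sprintf("%s_%s", retained$participant_id, retained$date)
  plan$key <- sprintf("%s_%s", plan$participant_id, plan$date)
  plan_r <- plan[plan$key %in% retained$key, ]

  roles <- ifelse(plan_r$participant_id %in% fplan$test_ids, "test", "train")
  test_days <- which(roles == "test")
  fp_pick <- integer(0)
  if (length(test_days) > 0 && cfg$fp_hours > 0) {
    fp_pick <- with_seed(derive_seed(fold_seed, 2), {
      sample(test_days, min(cfg$fp_hours, length(test_days)))
    })
  }

  harvests <- purrr::map(seq_len(nrow(plan_r)), function(i) {
    harvest_day(plan_r[i, ], roles[i], cfg, with_fp_hour = i %in% fp_pick,
                seed = derive_seed(fold_seed, 3000 + i))
  })

  is_test <- roles == "test"
  fit_meta <- purrr::map_dfr(harvests[!is_test], "fit_meta")
  fit_sig <- bind_signal_arrays(purrr::map(harvests[!is_test], "fit_signals"))
  say("  training windows: %d (%d positive)", nrow(fit_meta),
      sum(fit_meta$label == 1))

  fit_win <- fit_meta
  class(fit_win) <- c("wf_windows", class(fit_win))
  spec <- cnn_spec(
    input_length = as.integer(round(cfg$window_seconds *
                                      cfg$generator$sampling_rate_hz)),
    input_channels = n_channels_of(cfg$channels)
  )
  ens <- train_ensemble(fit_win, fit_sig, fplan, spec, cfg$training,
                        cfg$transforms, seed = derive_seed(fold_seed, 7))

  # ---- window-level evaluation ----
  eval_meta <- purrr::map_dfr(harvests[is_test], "eval_meta")
  eval_sig <- bind_signal_arrays(purrr::map(harvests[is_test], "eval_signals"))
  pr <- predict_ensemble(ens, eval_sig, per_member = TRUE)
  scored_eval <- dplyr::mutate(eval_meta, score = pr$score)
  wm <- window_metrics(scored_eval)
  member_aucs <- tibble::tibble(
    member = seq_len(ncol(pr$member_scores)),
    auc = apply(pr$member_scores, 2, roc_auc, labels = eval_meta$label)
  )
  say("  window AUC %.3f (members %s)", wm$auc,
      paste(sprintf("%.3f", member_aucs$auc), collapse = ", "))

  # ---- meal-level aggregation ----
  region_scores <- purrr::map_dfr(harvests[is_test], function(h) {
    if (is.null(h$region_meta)) return(NULL)
    sc <- predict_ensemble(ens, h$region_signals)
    purrr::map_dfr(seq_len(nrow(h$region_meta)), function(i) {
      rws <- h$region_rows[[i]]
      tibble::tibble(
        participant_id = h$participant_id, date = h$date,
        start_ts = h$region_meta$start_ts[i], end_ts = h$region_meta$end_ts[i],
        is_meal = h$region_meta$is_meal[i],
        mean_score = if (length(rws) > 0) mean(sc[rws]) else NA_real_,
        n_windows = length(rws)
      )
    })
  })
  region_scores <- region_scores[!is.na(region_scores$mean_score), ]
  meal_metrics <- if (nrow(region_scores) > 0 &&
                        length(unique(region_scores$is_meal)) > 1) {
    window_metrics(region_scores, score = "mean_score", label = "is_meal")
  } else {
    window_metrics(tibble::tibble(score = numeric(), label = integer()))[0, ]
  }
  if (nrow(meal_metrics) > 0) say("  meal AUC %.3f on %d regions",
                                  meal_metrics$auc, nrow(region_scores))

  # ---- alarm logic ----
  recall <- purrr::map_dfr(harvests[is_test], function(h) {
    if (is.null(h$recall_meta)) return(NULL)
    sc <- predict_ensemble(ens, h$recall_signals)
    stream <- dplyr::mutate(h$recall_meta, score = sc)
    purrr::map_dfr(seq_len(nrow(h$recall_meals)), function(i) {
      st <- stream[stream$meal == as.character(i), ]
      cr <- call_recall(st, h$recall_meals[i, ], cfg$call)
      dplyr::mutate(cr, participant_id = h$participant_id, date = h$date)
    })
  })

  fp_rate <- {
    streams <- purrr::compact(purrr::map(harvests[is_test], function(h) {
      if (is.null(h$fp_meta)) return(NULL)
      dplyr::mutate(h$fp_meta, score = predict_ensemble(ens, h$fp_signals))
    }))
    hours <- length(streams)
    if (hours > 0) {
      tibble::tibble(
        calls_per_hour = false_positive_rate(streams, cfg$call, total_hours = hours),
        hours = hours
      )
    } else {
      tibble::tibble(calls_per_hour = NA_real_, hours = 0)
    }
  }

  list(window_metrics = wm, member_aucs = member_aucs,
       region_scores = region_scores, meal_metrics = meal_metrics,
       recall = recall, fp_rate = fp_rate, scored_eval = scored_eval,
       ensemble = ens)
}

#' Personal fine-tuning experiment
#'
#' Trains a global ensemble on every retained participant except the
#' target, then fine-tunes it on the target's 60% day split and compares
#' global versus personalized window AUC on the held-out 20% test days.
#'
#' @param cfg An [experiment_config()].
#' @param target_id Participant to personalize (default: last planned id).
#' @param gesture_shift Extra jitter applied to the target's gesture
#'   parameters, emulating an individual whose eating kinematics differ
#'   from the population the global model saw.
#' @param n_replicates Seeded fine-tuning replicates (day split and
#'   training randomness redrawn each time).
#' @return A `wf_personal_report`: tibble with one row per replicate
#'   (`replicate`, `auc_global`, `auc_personal`) plus the day counts used.
#' @export
personalization_experiment <- function(cfg = experiment_config(),
                                       target_id = NULL,
                                       gesture_shift = 2,
                                       n_replicates = 5) {
  master <- cfg$master_seed
  plan <- cohort_plan(cfg$n_participants, cfg$days_per_participant,
                      cfg$generator, seed = derive_seed(master, 1),
                      gesture_spread = cfg$gesture_spread)
  target_id <- target_id %||% tail(plan$participant_id, 1)
  # shift the target's gesture parameters away from the population
  shifted <- with_seed(derive_seed(master, 5), jitter_gesture(gesture_shift))
  plan$gesture[plan$participant_id == target_id] <-
    list(shifted)[rep(1, sum(plan$participant_id == target_id))]

  others <- setdiff(unique(plan$participant_id), target_id)
  fplan <- split_plan(others, n_test = 0, n_val = cfg$n_val,
                      n_members = cfg$n_members,
                      test_ids = character(0),
                      seed = derive_seed(master, 6))

  plan$key <- sprintf("%s_%s", plan$participant_id, plan$date)
  roles <- ifelse(plan$participant_id == target_id, "test", "train")
  harvests <- purrr::map(seq_len(nrow(plan)), function(i) {
    harvest_day(plan[i, ], ifelse(roles[i] == "test", "train", roles[i]), cfg,
                with_fp_hour = FALSE, seed = derive_seed(master, 5000 + i))
  })

  is_target <- roles == "test"
  fit_meta <- purrr::map_dfr(harvests[!is_target], "fit_meta")
  fit_sig <- bind_signal_arrays(purrr::map(harvests[!is_target], "fit_signals"))
  fit_win <- fit_meta
  class(fit_win) <- c("wf_windows", class(fit_win))
  spec <- cnn_spec(
    input_length = as.integer(round(cfg$window_seconds *
                                      cfg$generator$sampling_rate_hz)),
    input_channels = n_channels_of(cfg$channels)
  )
  global <- train_ensemble(fit_win, fit_sig, fplan, spec, cfg$training,
                           cfg$transforms, seed = derive_seed(master, 7))

  tgt_meta <- purrr::map_dfr(harvests[is_target], "fit_meta")
  tgt_sig <- bind_signal_arrays(purrr::map(harvests[is_target], "fit_signals"))
  tgt_win <- tgt_meta
  class(tgt_win) <- c("wf_windows", class(tgt_win))

  rows <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    ft <- finetune_ensemble(global, tgt_win, tgt_sig, cfg$training,
                            seed = derive_seed(master, 8000 + r))
    te <- ft$test_rows
    if (length(te) == 0 || length(unique(tgt_win$label[te])) < 2) {
      return(tibble::tibble(replicate = r, auc_global = NA_real_,
                            auc_personal = NA_real_,
                            n_test_windows = length(te)))
    }
    x_te <- tgt_sig[te, , , drop = FALSE]
    y_te <- tgt_win$label[te]
    tibble::tibble(
      replicate = r,
      auc_global = roc_auc(predict_ensemble(global, x_te), y_te),
      auc_personal = roc_auc(predict_ensemble(ft$ensemble, x_te), y_te),
      n_test_windows = length(te)
    )
  })
  structure(list(replicates = rows, target_id = target_id,
                 n_days = cfg$days_per_participant),
            class = "wf_personal_report")
}

#' @export
print.wf_personal_report <- function(x, ...) {
  cat(sprintf("personalization of %s over %d replicate(s):\n", x$target_id,
              nrow(x$replicates)))
  print(x$replicates)
  invisible(x)
}

#' @export
print.wf_report <- function(x, ...) {
  cat("eating-detection experiment report\n")
  cat(sprintf("  folds: %d (%s)\n", length(x$folds), x$config$mode))
  wm <- x$window_metrics
  cat(sprintf("  window AUC: %s\n",
              paste(sprintf("%.3f", wm$auc), collapse = ", ")))
  if (nrow(x$meal_metrics) > 0) {
    cat(sprintf("  meal AUC:   %s\n",
                paste(sprintf("%.3f", x$meal_metrics$auc), collapse = ", ")))
  }
  if (nrow(x$recall) > 0) {
    cat(sprintf("  %d-min call recall: %.3f (%d meals)\n",
                x$config$call$horizon_minutes, mean(x$recall$recalled),
                nrow(x$recall)))
  }
  if (nrow(x$fp_rate) > 0 && any(is.finite(x$fp_rate$calls_per_hour))) {
    cat(sprintf("  false positives/hour: %.3f over %d negative hour(s)\n",
                stats::weighted.mean(x$fp_rate$calls_per_hour, x$fp_rate$hours,
                                     na.rm = TRUE),
                sum(x$fp_rate$hours)))
  }
  invisible(x)
}

#' @export
tidy.wf_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidyr::pivot_longer(x$window_metrics,
                                      cols = -dplyr::any_of("fold"),
                                      names_to = "metric"),
                  level = "window"),
    if (nrow(x$meal_metrics) > 0) {
      dplyr::mutate(tidyr::pivot_longer(x$meal_metrics,
                                        cols = -dplyr::any_of("fold"),
                                        names_to = "metric"),
                    level = "meal")
    }
  )
}

#' @export
glance.wf_report <- function(x, ...) {
  tibble::tibble(
    folds = length(x$folds),
    window_auc = mean(x$window_metrics$auc),
    window_auprc = mean(x$window_metrics$auprc),
    meal_auc = if (nrow(x$meal_metrics) > 0) mean(x$meal_metrics$auc) else NA_real_,
    recall = if (nrow(x$recall) > 0) mean(x$recall$recalled) else NA_real_,
    fp_per_hour = if (nrow(x$fp_rate) > 0)
      stats::weighted.mean(x$fp_rate$calls_per_hour, x$fp_rate$hours, na.rm = TRUE)
      else NA_real_
  )
}
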