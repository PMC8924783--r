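#' Total recorded duration of a day in hours
#'
#' Sums the recorded span of each session (last minus first timestamp plus
#' one sample period), so diary gaps between sessions do not count as wear
#' time.
#'
#' @param day A sensor-day tibble.
#' @return Hours of recording (scalar).
#' @export
day_duration_hours <- function(day) {
  if (nrow(day) == 0) return(0)
  period_ms <- stats::median(diff(day$ts))
  if (!is.finite(period_ms)) period_ms <- 0
  spans <- day |>
    dplyr::group_by(.data$sesid) |>
    dplyr::summarise(span = max(.data$ts) - min(.data$ts) + period_ms,
                     .groups = "drop")
  sum(spans$span) / 3.6e6
}

#' Detect watch-off (near-zero signal) segments
#'
#' Flags stretches where the rolling mean of the summed absolute motion
#' signal stays below a tiny threshold for at least `min_minutes`, which is
#' the signature of a watch taken off the wrist. Detection is for reporting
#' only; no samples are removed.
#'
#' @param day A sensor-day tibble.
#' @param threshold Mean |accl| + |gyro| level (default 1e-3) below which a
#'   sample counts as silent.
#' @param min_minutes Minimum silent run length to report (default 5).
#' @return Tibble of segments: `start_ts`, `end_ts`, `minutes`.
#' @export
detect_watch_off <- function(day, threshold = 1e-3, min_minutes = 5) {
  empty <- tibble::tibble(start_ts = double(), end_ts = double(), minutes = double())
  if (nrow(day) == 0) return(empty)
  level <- rowSums(abs(as.matrix(day[motion_cols()])))
  rate <- 1000 / stats::median(diff(day$ts))
  w <- max(1L, round(rate * 300))
  roll <- as.numeric(stats::filter(level, rep(1 / w, w), sides = 2))
  roll[is.na(roll)] <- level[is.na(roll)]
  silent <- roll < threshold * 6
  r <- rle(silent)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / rate >= min_minutes * 60)
  if (!any(keep)) return(empty)
  tibble::tibble(
    start_ts = day$ts[starts[keep]],
    end_ts = day$ts[ends[keep]],
    minutes = r$lengths[keep] / rate / 60
  )
}

#' Apply participant- and day-level exclusion rules to a cohort
#'
#' Exclusions are applied in order: (a) participants whose fraction of
#' retrospectively tagged meals, pooled over their days, strictly exceeds
#' `retro_threshold`; (b) days whose total recorded duration is below
#' `min_day_hours`; (c) days with no meal events at all. Exactly 50%
#' retrospective is retained (the rule is a strict `>`). Watch-off segments
#' are detected and reported but never removed.
#'
#' @param days List of sensor-day tibbles (or a `wf_cohort`).
#' @param retro_threshold Retrospective-meal fraction above which a
#'   participant is dropped (default 0.5).
#' @param min_day_hours Minimum recorded hours per day (default 3).
#' @return A list with `days` (retained sensor days) and `report`
#'   (`wf_cleaning_report`): tibbles `excluded` (`participant_id`, `date`,
#'   `reason`), `retained`, and `watch_off` segments.
#' @export
clean_cohort <- function(days, retro_threshold = 0.5, min_day_hours = 3) {
  if (inherits(days, "wf_cohort")) days <- days$days
  report_empty <- structure(
    list(
      excluded = tibble::tibble(participant_id = character(),
                                date = as.Date(character()), reason = character()),
      retained = tibble::tibble(participant_id = character(),
                                date = as.Date(character())),
      watch_off = tibble::tibble(participant_id = character(),
                                 date = as.Date(character()),
                                 start_ts = double(), end_ts = double(),
                                 minutes = double())
    ),
    class = "wf_cleaning_report"
  )
  if (length(days) == 0) return(list(days = list(), report = report_empty))

  info <- purrr::map_dfr(days, function(d) {
    meals <- extract_meals(d)
    tibble::tibble(
      participant_id = d$participant_id[1],
      date = d$date[1],
      n_meals = nrow(meals),
      n_retro = sum(meals$retrospective),
      hours = day_duration_hours(d)
    )
  })
  info$key <- sprintf("%s_%s", info$participant_id, info$date)

  by_part <- info |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_meals = sum(.data$n_meals), n_retro = sum(.data$n_retro),
                     .groups = "drop") |>
    dplyr::mutate(retro_frac = ifelse(.data$n_meals > 0,
                                      .data$n_retro / .data$n_meals, 0))
  bad_participants <- by_part$participant_id[by_part$retro_frac > retro_threshold]

  excl <- list()
  if (length(bad_participants) > 0) {
    excl$retro <- info |>
      dplyr::filter(.data$participant_id %in% bad_participants) |>
      dplyr::transmute(.data$participant_id, .data$date,
                       reason = sprintf("retro>%d%%", round(retro_threshold * 100)))
  }
  rest <- dplyr::filter(info, !.data$participant_id %in% bad_participants)
  short <- dplyr::filter(rest, .data$hours < min_day_hours)
  if (nrow(short) > 0) {
    excl$short <- dplyr::transmute(short, .data$participant_id, .data$date,
                                   reason = sprintf("<%g h", min_day_hours))
  }
  rest <- dplyr::filter(rest, .data$hours >= min_day_hours)
  nomeal <- dplyr::filter(rest, .data$n_meals == 0)
  if (nrow(nomeal) > 0) {
    excl$nomeal <- dplyr::transmute(nomeal, .data$participant_id, .data$date,
                                    reason = "no-meals")
  }
  rest <- dplyr::filter(rest, .data$n_meals > 0)

  watch_off <- purrr::map_dfr(days[match(rest$key, info$key)], function(d) {
    seg <- detect_watch_off(d)
    if (nrow(seg) == 0) return(NULL)
    dplyr::bind_cols(
      tibble::tibble(participant_id = d$participant_id[1], date = d$date[1]),
      seg
    )
  })
  if (nrow(watch_off) == 0) watch_off <- report_empty$watch_off

  report <- structure(
    list(
      excluded = dplyr::bind_rows(excl) %||% report_empty$excluded,
      retained = dplyr::select(rest, "participant_id", "date"),
      watch_off = watch_off
    ),
    class = "wf_cleaning_report"
  )
  if (nrow(report$excluded) == 0) report$excluded <- report_empty$excluded
  list(days = days[match(rest$key, info$key)], report = report)
}

#' @export
print.wf_cleaning_report <- function(x, ...) {
  cat(sprintf("cleaning report: %d retained, %d excluded day(s)\n",
              nrow(x$retained), nrow(x$excluded)))
  if (nrow(x$excluded) > 0) print(dplyr::count(x$excluded, .data$reason))
  if (nrow(x$watch_off) > 0) {
    cat(sprintf("watch-off segments detected on %d day(s)\n",
                dplyr::n_distinct(paste(x$watch_off$participant_id, x$watch_off$date))))
  }
  invisible(x)
}

#' @export
tidy.wf_cleaning_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$retained, reason = NA_character_, retained = TRUE),
    dplyr::mutate(x$excluded, retained = FALSE)
  )
}
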