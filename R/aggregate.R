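#' Alarm ("call") configuration
#'
#' A call is raised over a horizon-length span when strictly more than
#' `n_windows` windows inside it score above `score_cutoff`; windows advance
#' at `step_seconds`. One hour of 10-second steps yields 360 candidate
#' chunks.
#'
#' @param step_seconds Stride between scored windows (default 10).
#' @param score_cutoff Score above which a window counts as positive
#'   (default 0.3).
#' @param n_windows Strict count threshold N; a span needs > N positive
#'   windows (default 3).
#' @param horizon_minutes Span length in minutes, 5 or 10 (default 5).
#' @return A `wf_call_config` list.
#' @export
call_config <- function(step_seconds = 10, score_cutoff = 0.3, n_windows = 3,
                        horizon_minutes = 5) {
  if (!is_prob(score_cutoff) || score_cutoff <= 0 || score_cutoff >= 1) {
    abort("`score_cutoff` must lie in (0, 1).", class = "wristfork_config_error")
  }
  if (n_windows < 1) abort("`n_windows` must be >= 1.", class = "wristfork_config_error")
  stopifnot_scalar_number(step_seconds, "step_seconds", positive = TRUE)
  stopifnot_scalar_number(horizon_minutes, "horizon_minutes", positive = TRUE)
  structure(list(step_seconds = step_seconds, score_cutoff = score_cutoff,
                 n_windows = n_windows, horizon_minutes = horizon_minutes),
            class = "wf_call_config")
}

#' Aggregate window scores over meals and matched negative regions
#'
#' For each meal the mean score of the windows whose midpoint falls inside
#' it becomes the region score. An equal number of negative regions with the
#' identical length multiset is then sampled from non-meal time on the same
#' participant-days, avoiding a `buffer_minutes` guard band around every
#' meal, and scored the same way. Comparing positive and matched negative
#' region scores gives the meal-level detection performance.
#'
#' @param scored_windows Data frame of scored windows: `participant_id`,
#'   `date`, `start_ts`, `end_ts`, `score`.
#' @param meals Meal events to score (see [extract_meals()]); retrospective
#'   meals should be filtered out by the caller when not wanted.
#' @param buffer_minutes Guard band around meals that negative regions must
#'   avoid (default 10).
#' @param tries Placement attempts per negative region.
#' @param seed Optional seed for the negative-region draw.
#' @return A `wf_region_scores` tibble: `participant_id`, `date`,
#'   `start_ts`, `end_ts`, `is_meal`, `mean_score`, `n_windows`.
#' @export
score_meals <- function(scored_windows, meals, buffer_minutes = 10,
                        tries = 200, seed = NULL) {
  if (nrow(meals) == 0) abort("no meals to score.", class = "wristfork_usage_error")
  sw <- scored_windows
  sw$mid_ts <- (sw$start_ts + sw$end_ts) / 2
  sw$day_key <- sprintf("%s_%s", sw$participant_id, sw$date)
  meals$day_key <- sprintf("%s_%s", meals$participant_id, meals$date)

  region_score <- function(day_key, a, b) {
    m <- sw$day_key == day_key & sw$mid_ts >= a & sw$mid_ts < b
    list(score = if (any(m)) mean(sw$score[m]) else NA_real_, n = sum(m))
  }

  pos <- purrr::map_dfr(seq_len(nrow(meals)), function(i) {
    rs <- region_score(meals$day_key[i], meals$start_ts[i], meals$end_ts[i])
    tibble::tibble(
      participant_id = meals$participant_id[i], date = meals$date[i],
      start_ts = meals$start_ts[i], end_ts = meals$end_ts[i],
      is_meal = TRUE, mean_score = rs$score, n_windows = rs$n
    )
  })

  buffer_ms <- buffer_minutes * 60000
  day_extent <- sw |>
    dplyr::group_by(.data$day_key) |>
    dplyr::summarise(lo = min(.data$start_ts), hi = max(.data$end_ts),
                     .groups = "drop")

  neg <- with_seed(seed, purrr::map_dfr(seq_len(nrow(meals)), function(i) {
    key <- meals$day_key[i]
    len <- meals$end_ts[i] - meals$start_ts[i]
    ext <- day_extent[day_extent$day_key == key, ]
    day_meals <- meals[meals$day_key == key, ]
    if (nrow(ext) == 0) return(NULL)
    for (t in seq_len(tries)) {
      a <- runif(1, ext$lo, ext$hi - len)
      b <- a + len
      clash <- any(a < day_meals$end_ts + buffer_ms &
                     b > day_meals$start_ts - buffer_ms)
      if (clash) next
      rs <- region_score(key, a, b)
      if (rs$n == 0) next
      return(tibble::tibble(
        participant_id = meals$participant_id[i], date = meals$date[i],
        start_ts = a, end_ts = b, is_meal = FALSE,
        mean_score = rs$score, n_windows = rs$n
      ))
    }
    NULL
  }))

  if (is.null(neg) || nrow(neg) < nrow(meals)) {
    n_missing <- nrow(meals) - (if (is.null(neg)) 0 else nrow(neg))
    abort(sprintf(
      "could not place matched negative regions for %d meal(s); too little negative time.",
      n_missing), class = "wristfork_usage_error")
  }
  out <- dplyr::bind_rows(pos, neg)
  class(out) <- c("wf_region_scores", class(out))
  out
}

# positive-window counts per horizon-span start over a 10-s grid
span_counts <- function(stream, cfg) {
  stream <- dplyr::arrange(stream, .data$start_ts)
  pos_ts <- stream$start_ts[stream$score > cfg$score_cutoff]
  horizon_ms <- cfg$horizon_minutes * 60000
  starts <- stream$start_ts
  counts <- findInterval(starts + horizon_ms - 1e-6, pos_ts) -
    findInterval(starts - 1e-6, pos_ts)
  tibble::tibble(span_start = starts, n_positive = counts)
}

#' Detect alarm calls on a scored stream
#'
#' Slides a `horizon_minutes` span across windows scored at
#' `step_seconds` spacing; any span containing strictly more than
#' `n_windows` above-cutoff windows raises a call. Qualifying spans closer
#' than one horizon apart merge into a single call region, so one sustained
#' detection is counted once.
#'
#' @param stream Data frame of one day's scored windows at the call stride:
#'   `start_ts`, `score` (one participant-day at a time).
#' @param cfg A [call_config()].
#' @return Tibble of call regions: `start_ts`, `end_ts`, `n_spans`.
#' @export
detect_calls <- function(stream, cfg = call_config()) {
  empty <- tibble::tibble(start_ts = double(), end_ts = double(), n_spans = integer())
  if (nrow(stream) == 0) return(empty)
  sc <- span_counts(stream, cfg)
  hit <- sc$n_positive > cfg$n_windows
  if (!any(hit)) return(empty)
  ts_hit <- sc$span_start[hit]
  horizon_ms <- cfg$horizon_minutes * 60000
  new_region <- c(TRUE, diff(ts_hit) >= horizon_ms)
  region_id <- cumsum(new_region)
  tibble::tibble(ts = ts_hit, region = region_id) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(start_ts = min(.data$ts),
                     end_ts = max(.data$ts) + horizon_ms,
                     n_spans = dplyr::n(), .groups = "drop") |>
    dplyr::select("start_ts", "end_ts", "n_spans")
}

#' Per-meal call recall
#'
#' A meal is recalled when strictly more than `n_windows` windows score
#' above the cutoff within the first `horizon_minutes` after its diary
#' start.
#'
#' @param stream Scored windows at the call stride for the meal's day:
#'   `start_ts`, `score`.
#' @param meals Meal events on that day.
#' @param cfg A [call_config()].
#' @return Tibble with one row per meal: `start_ts`, `n_positive`,
#'   `recalled`.
#' @export
call_recall <- function(stream, meals, cfg = call_config()) {
  horizon_ms <- cfg$horizon_minutes * 60000
  pos_ts <- sort(stream$start_ts[stream$score > cfg$score_cutoff])
  purrr::map_dfr(seq_len(nrow(meals)), function(i) {
    a <- meals$start_ts[i]
    k <- findInterval(a + horizon_ms - 1e-6, pos_ts) - findInterval(a - 1e-6, pos_ts)
    tibble::tibble(start_ts = a, n_positive = k, recalled = k > cfg$n_windows)
  })
}

#' Hourly false-positive call rate on negative time
#'
#' Counts distinct call regions (see [detect_calls()]) raised on a stream
#' that contains no true meals -- meal neighborhoods are expected to have
#' been excised with their 10-minute guard bands -- and divides by the
#' evaluated hours. A maximal cluster of qualifying spans counts once.
#'
#' @param stream Scored negative-time windows at the call stride:
#'   `start_ts`, `score`; a list of such frames is treated as independent
#'   negative stretches.
#' @param cfg A [call_config()].
#' @param total_hours Hours of negative time evaluated.
#' @param positive_regions Number of true-positive regions to subtract from
#'   the false-region count (default 0: on purely negative streams the
#'   subtraction in the rate definition is vacuous).
#' @return Calls per hour (scalar).
#' @export
false_positive_rate <- function(stream, cfg = call_config(), total_hours,
                                positive_regions = 0) {
  if (!is.numeric(total_hours) || total_hours <= 0) {
    abort("`total_hours` must be positive.", class = "wristfork_usage_error")
  }
  streams <- if (is.data.frame(stream)) list(stream) else stream
  n_regions <- sum(vapply(streams, function(s) nrow(detect_calls(s, cfg)),
                          numeric(1)))
  max(0, n_regions - positive_regions) / total_hours
}
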