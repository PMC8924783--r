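#' Cut a sensor day into fixed sliding windows with 1/0/-1 labels
#'
#' Windows are `window_seconds` long, advance by `step_seconds` from the
#' first sample of the day over the concatenated sample timeline, and are
#' labeled:
#' * `1` when strictly more than half the window's time is tagged mealtime
#'   (at the defaults, > 150 s of a 300 s window);
#' * `-1` when the window (a) spans two recording sessions, (b) overlaps any
#'   sample whose `tagRetro` is set, or (c) overlaps a meal shorter than
#'   `min_meal_seconds` -- such windows are excluded from both training and
#'   evaluation but kept in the set for audit;
#' * `0` otherwise.
#'
#' A day shorter than one window yields an empty window set.
#'
#' @param day A sensor-day tibble.
#' @param window_seconds Window length in seconds (default 300).
#' @param step_seconds Moving step in seconds (default 20).
#' @param min_meal_seconds Meals shorter than this exclude their windows
#'   (default 180).
#' @return A `wf_windows` tibble: `participant_id`, `date`, `window_id`,
#'   `start_ts`, `end_ts`, `start_idx`, `end_idx` (sample rows in `day`),
#'   `label`, `meal_id` (row in [extract_meals()] output when > half the
#'   window is that meal, else `NA`), plus attributes `window_seconds`,
#'   `step_seconds`, `rate_hz`.
#' @export
make_windows <- function(day, window_seconds = 300, step_seconds = 20,
                         min_meal_seconds = 180) {
  stopifnot_scalar_number(window_seconds, "window_seconds", positive = TRUE)
  stopifnot_scalar_number(step_seconds, "step_seconds", positive = TRUE)
  rate <- if (nrow(day) > 1) 1000 / stats::median(diff(day$ts)) else NA_real_
  n_win_samples <- if (is.finite(rate)) as.integer(round(window_seconds * rate)) else Inf
  step_samples <- if (is.finite(rate)) max(1L, as.integer(round(step_seconds * rate))) else 1L

  empty <- tibble::tibble(
    participant_id = character(), date = as.Date(character()),
    window_id = integer(), start_ts = double(), end_ts = double(),
    start_idx = integer(), end_idx = integer(), label = integer(),
    meal_id = integer()
  )
  attr(empty, "window_seconds") <- window_seconds
  attr(empty, "step_seconds") <- step_seconds
  attr(empty, "rate_hz") <- rate
  class(empty) <- c("wf_windows", class(empty))
  if (nrow(day) < n_win_samples || !is.finite(rate)) return(empty)

  n <- nrow(day)
  starts <- seq.int(1L, n - n_win_samples + 1L, by = step_samples)
  ends <- starts + n_win_samples - 1L

  tag <- day$tag
  retro_set <- as.integer(!is.na(day$tagRetro) & day$tagRetro != 0)
  csum_tag <- c(0, cumsum(tag))
  csum_retro <- c(0, cumsum(retro_set))

  meals <- extract_meals(day)
  short_meal <- rep(FALSE, n)
  meal_of_sample <- rep(NA_integer_, n)
  if (nrow(meals) > 0) {
    for (m in seq_len(nrow(meals))) {
      idx <- which(day$ts >= meals$start_ts[m] & day$ts < meals$end_ts[m])
      meal_of_sample[idx] <- m
      if ((meals$end_ts[m] - meals$start_ts[m]) / 1000 < min_meal_seconds) {
        short_meal[idx] <- TRUE
      }
    }
  }
  csum_short <- c(0, cumsum(as.integer(short_meal)))

  tag_count <- csum_tag[ends + 1L] - csum_tag[starts]
  retro_count <- csum_retro[ends + 1L] - csum_retro[starts]
  short_count <- csum_short[ends + 1L] - csum_short[starts]
  cross_session <- day$sesid[ends] != day$sesid[starts]

  label <- ifelse(tag_count / rate > window_seconds / 2, 1L, 0L)
  label[cross_session | retro_count > 0 | short_count > 0] <- -1L

  meal_id <- rep(NA_integer_, length(starts))
  pos <- which(label == 1L)
  if (length(pos) > 0 && nrow(meals) > 0) {
    meal_id[pos] <- vapply(pos, function(k) {
      ids <- meal_of_sample[starts[k]:ends[k]]
      ids <- ids[!is.na(ids)]
      if (length(ids) == 0) NA_integer_ else as.integer(names(which.max(table(ids))))
    }, integer(1))
  }

  out <- tibble::tibble(
    participant_id = day$participant_id[1],
    date = day$date[1],
    window_id = seq_along(starts),
    start_ts = day$ts[starts],
    end_ts = day$ts[ends] + 1000 / rate,
    start_idx = starts,
    end_idx = ends,
    label = label,
    meal_id = meal_id
  )
  attr(out, "window_seconds") <- window_seconds
  attr(out, "step_seconds") <- step_seconds
  attr(out, "rate_hz") <- rate
  class(out) <- c("wf_windows", class(out))
  out
}

#' Window-set bookkeeping
#'
#' @param x A `wf_windows` tibble.
#' @param ... Unused.
#' @return One-row tibble with `total`, `positives`, `negatives`, `excluded`.
#' @export
glance.wf_windows <- function(x, ...) {
  tibble::tibble(
    total = nrow(x),
    positives = sum(x$label == 1L),
    negatives = sum(x$label == 0L),
    excluded = sum(x$label == -1L)
  )
}

#' Balance a training window set by oversampling positives
#'
#' Appends `N = #negatives - #positives` copies of positive windows drawn
#' with replacement, so that positives match negatives exactly. The original
#' windows are left untouched; appended rows are marked `oversampled = TRUE`.
#' Expects a training set from which `-1` windows have already been removed.
#'
#' @param windows A `wf_windows` tibble with labels in \{0, 1\}.
#' @param seed Optional seed for the resampling draw.
#' @return The balanced `wf_windows` tibble.
#' @export
oversample_windows <- function(windows, seed = NULL) {
  if (any(windows$label == -1L)) {
    abort("remove -1 (excluded) windows before oversampling.",
          class = "wristfork_usage_error")
  }
  n_pos <- sum(windows$label == 1L)
  n_neg <- sum(windows$label == 0L)
  if (n_pos == 0) {
    abort("cannot balance a training set with zero positive windows.",
          class = "wristfork_usage_error")
  }
  if (n_pos > n_neg) {
    warn("positives already outnumber negatives; no oversampling applied.")
    windows$oversampled <- FALSE
    return(windows)
  }
  windows$oversampled <- FALSE
  n_add <- n_neg - n_pos
  if (n_add == 0) return(windows)
  with_seed(seed, {
    pick <- sample(which(windows$label == 1L), n_add, replace = TRUE)
    extra <- windows[pick, ]
    extra$oversampled <- TRUE
    out <- dplyr::bind_rows(windows, extra)
    attributes(out)[c("window_seconds", "step_seconds", "rate_hz")] <-
      attributes(windows)[c("window_seconds", "step_seconds", "rate_hz")]
    class(out) <- unique(c("wf_windows", class(out)))
    out
  })
}

#' Extract the channel matrices for a set of windows
#'
#' @param day The sensor-day tibble the windows were cut from.
#' @param windows A `wf_windows` tibble (rows must refer to `day`).
#' @param channels `"gyro"`, `"accl"`, or `"both"`.
#' @return Numeric array of shape (windows x samples x channels).
#' @export
window_signals <- function(day, windows, channels = c("gyro", "accl", "both")) {
  channels <- match.arg(channels)
  cols <- switch(channels,
    gyro = c("gyro_x", "gyro_y", "gyro_z"),
    accl = c("accl_x", "accl_y", "accl_z"),
    both = motion_cols()
  )
  sig <- as.matrix(day[cols])
  n_win <- nrow(windows)
  if (n_win == 0) return(array(0, dim = c(0, 0, length(cols))))
  len <- windows$end_idx[1] - windows$start_idx[1] + 1L
  out <- array(0, dim = c(n_win, len, length(cols)))
  for (i in seq_len(n_win)) {
    out[i, , ] <- sig[windows$start_idx[i]:windows$end_idx[i], ]
  }
  out
}
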