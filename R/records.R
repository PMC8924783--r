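#' Canonical sensor-record schema
#'
#' One participant-day of wrist-sensor data is a tibble ("sensor day") with a
#' `participant_id` and `date` column followed by the 18 physical record
#' columns: `ts` (epoch milliseconds), `tod` (seconds since local midnight),
#' `sesid` (recording-session index within the day), triaxial acceleration
#' `accl_x`/`accl_y`/`accl_z` in g, triaxial rotation rate
#' `gyro_x`/`gyro_y`/`gyro_z` in rad/s, six binary utensil flags
#' (`fork`, `knife`, `spoon`, `glass`, `chopstick`, `hand`), and the diary
#' labels `tag` (any eating tag), `tagTimely` (tag entered during eating) and
#' `tagRetro` (tag entered retrospectively; missing when never set).
#' Together with the participant id and date carried in the file name this
#' makes up the 20-feature record layout used throughout the package.
#'
#' @return Character vector of the 18 physical column names, in file order.
#' @export
record_schema <- function() {
  c(
    "ts", "tod", "sesid",
    "accl_x", "accl_y", "accl_z",
    "gyro_x", "gyro_y", "gyro_z",
    "fork", "knife", "spoon", "glass", "chopstick", "hand",
    "tag", "tagTimely", "tagRetro"
  )
}

utensil_cols <- function() c("fork", "knife", "spoon", "glass", "chopstick", "hand")
motion_cols <- function() c("accl_x", "accl_y", "accl_z", "gyro_x", "gyro_y", "gyro_z")

#' Assemble a sensor day from samples
#'
#' @param samples Data frame holding the 18 physical record columns.
#' @param participant_id Participant identifier (scalar character).
#' @param date Calendar date of the recording (`Date` or `"YYYY-MM-DD"`).
#' @param validate Run [validate_day()] on the result (default `TRUE`).
#' @return A sensor-day tibble (see [record_schema()]).
#' @export
sensor_day <- function(samples, participant_id, date, validate = TRUE) {
  missing_cols <- setdiff(record_schema(), names(samples))
  if (length(missing_cols) > 0) {
    abort(sprintf("samples are missing schema column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  day <- tibble::tibble(
    participant_id = as.character(participant_id),
    date = as.Date(date)
  )
  day <- dplyr::bind_cols(day, tibble::as_tibble(samples)[record_schema()])
  if (validate) validate_day(day)
  day
}

#' Validate a sensor day against the record invariants
#'
#' Checks that timestamps are strictly increasing, that session ids are
#' non-decreasing and advance exactly where the inter-sample gap exceeds the
#' session-gap threshold, that binary columns are 0/1, and that
#' `tagTimely <= tag`.
#'
#' @param day A sensor-day tibble.
#' @param session_gap_s Gap (seconds) between consecutive samples beyond which
#'   a new recording session must begin. Default 1 s.
#' @return The input, invisibly; aborts with the offending row index on
#'   violation.
#' @export
validate_day <- function(day, session_gap_s = 1) {
  missing_cols <- setdiff(c("participant_id", "date", record_schema()), names(day))
  if (length(missing_cols) > 0) {
    abort(sprintf("schema error: missing column(s) %s",
                  paste(missing_cols, collapse = ", ")),
          class = "wristfork_schema_error")
  }
  if (nrow(day) == 0) return(invisible(day))
  dts <- diff(day$ts)
  if (any(dts <= 0)) {
    k <- which(dts <= 0)[1] + 1L
    abort(sprintf("data error: `ts` not strictly increasing at row %d", k),
          class = "wristfork_data_error")
  }
  dses <- diff(day$sesid)
  if (any(dses < 0)) {
    k <- which(dses < 0)[1] + 1L
    abort(sprintf("data error: `sesid` decreases at row %d", k),
          class = "wristfork_data_error")
  }
  new_session <- dses > 0
  big_gap <- dts > session_gap_s * 1000
  bad <- which(new_session != big_gap)
  if (length(bad) > 0) {
    abort(sprintf(
      "data error: session boundary inconsistent with %gs gap rule at row %d",
      session_gap_s, bad[1] + 1L), class = "wristfork_data_error")
  }
  for (col in c(utensil_cols(), "tag", "tagTimely")) {
    v <- day[[col]]
    if (any(!v %in% c(0, 1))) {
      abort(sprintf("data error: column `%s` is not binary", col),
            class = "wristfork_data_error")
    }
  }
  retro <- day$tagRetro
  if (any(!is.na(retro) & !retro %in% c(0, 1))) {
    abort("data error: column `tagRetro` is not binary-or-missing",
          class = "wristfork_data_error")
  }
  if (any(day$tagTimely > day$tag)) {
    abort("data error: `tagTimely` exceeds `tag`", class = "wristfork_data_error")
  }
  invisible(day)
}

day_file_name <- function(participant_id, date) {
  sprintf("%s_%s.csv", participant_id, format(as.Date(date), "%Y-%m-%d"))
}

#' Write a sensor day to its delimited record file
#'
#' Files are named `<participant>_<YYYY-MM-DD>.csv` so that the participant id
#' and date complete the schema. A missing `tagRetro` is written as an empty
#' field.
#'
#' @param day A sensor-day tibble.
#' @param dir Output directory.
#' @return The file path, invisibly.
#' @export
write_day <- function(day, dir) {
  validate_day(day)
  path <- file.path(dir, day_file_name(day$participant_id[1], day$date[1]))
  out <- day[record_schema()]
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a sensor day from a delimited record file
#'
#' @param path Path to a `<participant>_<YYYY-MM-DD>.csv` record file.
#' @param validate Validate the result (default `TRUE`).
#' @return A sensor-day tibble.
#' @export
read_day <- function(path, validate = TRUE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  stem <- sub("\\.csv$", "", basename(path))
  m <- regmatches(stem, regexec("^(.+)_(\\d{4}-\\d{2}-\\d{2})$", stem))[[1]]
  if (length(m) != 3) {
    abort(sprintf("file name `%s` is not of the form <participant>_<YYYY-MM-DD>.csv",
                  basename(path)))
  }
  samples <- readr::read_csv(
    path,
    col_types = readr::cols(
      ts = readr::col_double(), tod = readr::col_double(),
      sesid = readr::col_integer(), .default = readr::col_double()
    ),
    na = c("", "NA"), progress = FALSE
  )
  missing_cols <- setdiff(record_schema(), names(samples))
  if (length(missing_cols) > 0) {
    abort(sprintf("schema error: missing column(s) %s",
                  paste(missing_cols, collapse = ", ")),
          class = "wristfork_schema_error")
  }
  day <- sensor_day(samples, m[2], m[3], validate = validate)
  day
}

#' Extract diary meal events from a sensor day
#'
#' Maximal runs of `tag == 1` become meal events; runs separated by even a
#' single untagged sample are distinct events. An event is retrospective iff
#' any of its samples has `tagRetro` set; its utensil set collects the utensil
#' flags active during the run. `end_ts` is the timestamp one sample period
#' past the last tagged sample, so a meal interval is `[start_ts, end_ts)`.
#'
#' @param day A sensor-day tibble.
#' @return Tibble of meal events: `participant_id`, `date`, `start_ts`,
#'   `end_ts`, `retrospective`, `utensils` (comma-joined label string).
#' @export
extract_meals <- function(day) {
  empty <- tibble::tibble(
    participant_id = character(), date = as.Date(character()),
    start_ts = double(), end_ts = double(),
    retrospective = logical(), utensils = character()
  )
  if (nrow(day) == 0 || !any(day$tag == 1)) return(empty)
  r <- rle(day$tag == 1)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  period_ms <- stats::median(diff(day$ts))
  purrr::map2_dfr(starts, ends, function(i, j) {
    seg <- day[i:j, ]
    uts <- utensil_cols()[colSums(seg[utensil_cols()]) > 0]
    tibble::tibble(
      participant_id = day$participant_id[1],
      date = day$date[1],
      start_ts = day$ts[i],
      end_ts = day$ts[j] + period_ms,
      retrospective = any(!is.na(seg$tagRetro) & seg$tagRetro == 1),
      utensils = paste(uts, collapse = ",")
    )
  })
}

#' Write or read a ground-truth meal sidecar
#'
#' The sidecar is a plain CSV listing one meal event per row; it is the
#' generator's record of truth and the reference for meal-level evaluation.
#'
#' @param meals Tibble of meal events as returned by [extract_meals()].
#' @param path CSV path.
#' @return `write_meals()` the path invisibly; `read_meals()` the tibble.
#' @export
write_meals <- function(meals, path) {
  readr::write_csv(meals, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_meals
#' @export
read_meals <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    date = readr::col_date(),
    start_ts = readr::col_double(),
    end_ts = readr::col_double(),
    retrospective = readr::col_logical(),
    utensils = readr::col_character()
  ), na = character(), progress = FALSE)
}
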