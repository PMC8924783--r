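#' Subject-wise split plan for ensemble training
#'
#' Holds out `n_test` participants as a fixed test set, then draws
#' `n_members` alternative splits of the remaining participants into
#' `n_val` validation subjects and training subjects. Each ensemble member
#' trains on one of these resampled splits while the test subjects never
#' move, so no participant ever appears in more than one of
#' train/validation/test for any member.
#'
#' @param participants Character vector of participant ids.
#' @param n_test,n_val Held-out test and per-member validation sizes
#'   (defaults 3 and 2, the 3/2/9-of-14 design).
#' @param n_members Ensemble size (default 5).
#' @param test_ids Optionally fix the test subjects instead of drawing them.
#' @param seed Optional seed.
#' @return A `wf_split_plan`: list with `test_ids` and a `members` tibble
#'   (`member`, `val_ids`, `train_ids` list-columns).
#' @export
split_plan <- function(participants, n_test = 3, n_val = 2, n_members = 5,
                       test_ids = NULL, seed = NULL) {
  participants <- unique(as.character(participants))
  if (length(participants) < n_test + n_val + 1) {
    abort("not enough participants for a test/validation/train split.",
          class = "wristfork_usage_error")
  }
  with_seed(seed, {
    if (is.null(test_ids)) {
      test_ids <- sort(sample(participants, n_test))
    } else {
      test_ids <- as.character(test_ids)
      if (!all(test_ids %in% participants)) {
        abort("`test_ids` must be drawn from `participants`.",
              class = "wristfork_usage_error")
      }
    }
    rest <- setdiff(participants, test_ids)
    members <- purrr::map_dfr(seq_len(n_members), function(m) {
      val <- sort(sample(rest, n_val))
      tibble::tibble(member = m, val_ids = list(val),
                     train_ids = list(sort(setdiff(rest, val))))
    })
    structure(list(test_ids = test_ids, members = members),
              class = "wf_split_plan")
  })
}

#' @export
print.wf_split_plan <- function(x, ...) {
  cat(sprintf("split plan: %d member(s); test = %s\n",
              nrow(x$members), paste(x$test_ids, collapse = ", ")))
  for (m in seq_len(nrow(x$members))) {
    cat(sprintf("  member %d: val = %s\n", m,
                paste(x$members$val_ids[[m]], collapse = ", ")))
  }
  invisible(x)
}

assert_split_hygiene <- function(plan) {
  for (m in seq_len(nrow(plan$members))) {
    ids <- list(plan$test_ids, plan$members$val_ids[[m]], plan$members$train_ids[[m]])
    all_ids <- unlist(ids)
    if (anyDuplicated(all_ids) > 0) {
      abort("split hygiene violated: a participant appears in two partitions.",
            class = "wristfork_usage_error")
    }
  }
  invisible(plan)
}

#' Train a 5-member ensemble on labeled windows
#'
#' Each member trains on its own resampled train/validation participant
#' split (the training partition is balanced by [oversample_windows()]; the
#' validation partition keeps its original imbalance) and the ensemble
#' score of a window is the arithmetic mean of the member scores.
#'
#' @param windows A `wf_windows` tibble with labels in \{0, 1\} (exclude
#'   `-1` windows first).
#' @param signals Signal array aligned with `windows` rows
#'   (windows x samples x channels).
#' @param plan A [split_plan()].
#' @param spec A [cnn_spec()].
#' @param config A [train_config()].
#' @param transforms A [transform_config()].
#' @param seed Optional seed governing member initialization, oversampling
#'   and training randomness.
#' @return A `wf_ensemble`: list with `members` (weights), `spec`,
#'   `transforms`, `plan`, `history`.
#' @export
train_ensemble <- function(windows, signals, plan, spec,
                           config = train_config(),
                           transforms = transform_config(), seed = NULL) {
  if (nrow(plan$members) < 1) {
    abort("split plan has no members.", class = "wristfork_usage_error")
  }
  assert_split_hygiene(plan)
  if (any(windows$label == -1L)) {
    abort("remove -1 windows before training.", class = "wristfork_usage_error")
  }
  members <- vector("list", nrow(plan$members))
  history <- list()
  for (m in seq_len(nrow(plan$members))) {
    tr_ids <- plan$members$train_ids[[m]]
    va_ids <- plan$members$val_ids[[m]]
    tr_rows <- which(windows$participant_id %in% tr_ids)
    va_rows <- which(windows$participant_id %in% va_ids)
    if (length(tr_rows) == 0 || length(va_rows) == 0) {
      abort("a member has an empty train or validation partition.",
            class = "wristfork_usage_error")
    }
    tr_win <- windows[tr_rows, ]
    tr_win$.row <- tr_rows
    tr_bal <- oversample_windows(tr_win, seed = derive_seed(seed %||% 0, 100 + m))
    x_tr <- signals[tr_bal$.row, , , drop = FALSE]
    y_tr <- tr_bal$label
    x_va <- signals[va_rows, , , drop = FALSE]
    y_va <- windows$label[va_rows]
    w0 <- init_cnn(spec, seed = derive_seed(seed %||% 0, 200 + m))
    cfg_m <- config
    cfg_m$seed <- derive_seed(seed %||% 0, 300 + m)
    fit <- train_cnn(w0, spec, x_tr, y_tr, x_va, y_va, cfg_m, transforms)
    members[[m]] <- fit$weights
    history[[m]] <- dplyr::mutate(fit$history, member = m,
                                  best_epoch = fit$best_epoch)
  }
  structure(list(members = members, spec = spec, transforms = transforms,
                 plan = plan, history = dplyr::bind_rows(history)),
            class = "wf_ensemble")
}

#' Score windows with an ensemble
#'
#' @param ensemble A `wf_ensemble`.
#' @param signals Signal array (windows x samples x channels).
#' @param per_member Also return the member-level score matrix.
#' @return Numeric vector of mean member scores, or a list
#'   `(score, member_scores)` when `per_member = TRUE`.
#' @export
predict_ensemble <- function(ensemble, signals, per_member = FALSE) {
  scores <- vapply(ensemble$members, function(w) {
    predict_cnn(w, ensemble$spec, signals, ensemble$transforms)
  }, numeric(dim(signals)[1]))
  scores <- matrix(scores, nrow = dim(signals)[1])
  avg <- rowMeans(scores)
  if (per_member) list(score = avg, member_scores = scores) else avg
}

#' @export
print.wf_ensemble <- function(x, ...) {
  cat(sprintf("ensemble of %d CNN member(s); input %d x %d; normalization %s\n",
              length(x$members), x$spec$input_length, x$spec$input_channels,
              x$transforms$normalization))
  invisible(x)
}

#' @export
tidy.wf_ensemble <- function(x, ...) x$history

#' @export
glance.wf_ensemble <- function(x, ...) {
  tibble::tibble(
    members = length(x$members),
    parameters = n_parameters(x$spec),
    input_length = x$spec$input_length,
    input_channels = x$spec$input_channels,
    normalization = x$transforms$normalization
  )
}

#' Fine-tune an ensemble into a personal model
#'
#' Splits the target individual's days 60/20/20 into fine-tuning,
#' validation and held-out test days, then continues training every member
#' for `config$finetune_epochs` (default 2) epochs on the fine-tuning days'
#' windows (balanced by oversampling), restoring each member's best
#' validation epoch. The individual must have been excluded from the
#' ensemble's own training.
#'
#' @param ensemble The global `wf_ensemble`.
#' @param windows The individual's `wf_windows` (labels in \{0, 1\}).
#' @param signals Signal array aligned with `windows`.
#' @param config A [train_config()] (`finetune_epochs` applies).
#' @param seed Optional seed for the day split and training randomness.
#' @return List: `ensemble` (personalized `wf_ensemble`), `day_split`
#'   (tibble of date/role), `test_rows` (window rows on held-out days).
#' @export
finetune_ensemble <- function(ensemble, windows, signals,
                              config = train_config(), seed = NULL) {
  days <- sort(unique(windows$date))
  if (length(days) < 5) {
    abort(paste0(
      "fine-tuning needs >= 5 recorded days for a 60/20/20 day split; ",
      "personal models are intended for individuals with >= 7 samples."),
      class = "wristfork_usage_error")
  }
  with_seed(seed, {
    n <- length(days)
    n_train <- floor(0.6 * n)
    n_val <- floor(0.2 * n)
    shuffled <- sample(days)
    roles <- rep("test", n)
    roles[seq_len(n_train)] <- "train"
    roles[n_train + seq_len(n_val)] <- "val"
    day_split <- tibble::tibble(date = shuffled, role = roles) |>
      dplyr::arrange(.data$date)

    tr_days <- day_split$date[day_split$role == "train"]
    va_days <- day_split$date[day_split$role == "val"]
    te_days <- day_split$date[day_split$role == "test"]
    tr_rows <- which(windows$date %in% tr_days)
    va_rows <- which(windows$date %in% va_days)
    te_rows <- which(windows$date %in% te_days)

    members <- ensemble$members
    history <- list()
    if (config$finetune_epochs > 0) {
      tr_win <- windows[tr_rows, ]
      tr_win$.row <- tr_rows
      tr_bal <- oversample_windows(tr_win, seed = derive_seed(seed %||% 0, 17))
      x_tr <- signals[tr_bal$.row, , , drop = FALSE]
      y_tr <- tr_bal$label
      x_va <- signals[va_rows, , , drop = FALSE]
      y_va <- windows$label[va_rows]
      for (m in seq_along(members)) {
        cfg_m <- config
        cfg_m$epochs <- config$finetune_epochs
        cfg_m$seed <- derive_seed(seed %||% 0, 400 + m)
        fit <- train_cnn(members[[m]], ensemble$spec, x_tr, y_tr, x_va, y_va,
                         cfg_m, ensemble$transforms)
        members[[m]] <- fit$weights
        history[[m]] <- dplyr::mutate(fit$history, member = m,
                                      best_epoch = fit$best_epoch)
      }
    }
    personal <- ensemble
    personal$members <- members
    personal$history <- if (length(history) > 0) dplyr::bind_rows(history)
                        else ensemble$history[0, ]
    list(ensemble = personal, day_split = day_split, test_rows = te_rows)
  })
}
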