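#' Plot a stretch of a sensor day
#'
#' Gyroscope and accelerometer traces with meal intervals shaded, handy for
#' eyeballing what the generator produced or what a model is looking at.
#'
#' @param day A sensor-day tibble.
#' @param from_tod,to_tod Optional time-of-day bounds in hours.
#' @param channels Columns to draw (default all six motion channels).
#' @return A ggplot object.
#' @export
plot_day <- function(day, from_tod = NULL, to_tod = NULL,
                     channels = motion_cols()) {
  d <- day
  if (!is.null(from_tod)) d <- d[d$tod >= from_tod * 3600, ]
  if (!is.null(to_tod)) d <- d[d$tod <= to_tod * 3600, ]
  meals <- extract_meals(day)
  long <- tidyr::pivot_longer(
    d[c("tod", channels, "tag")], dplyr::all_of(channels),
    names_to = "channel", values_to = "value"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$tod / 3600, y = .data$value))
  if (nrow(meals) > 0) {
    mday <- tibble::tibble(
      xmin = (meals$start_ts - day$ts[1]) / 3.6e6 + day$tod[1] / 3600,
      xmax = (meals$end_ts - day$ts[1]) / 3.6e6 + day$tod[1] / 3600
    )
    p <- p + ggplot2::geom_rect(
      data = mday, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf, ymax = Inf),
      fill = "orange", alpha = 0.25
    )
  }
  p +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time of day (h)", y = NULL,
                  title = sprintf("%s %s", day$participant_id[1], day$date[1]))
}

#' @export
autoplot.wf_region_scores <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$is_meal, y = .data$mean_score)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    ggplot2::labs(x = "meal region", y = "mean window score",
                  title = "meal-level aggregation scores")
}

roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- as.integer(as.logical(labels))[ord]
  tibble::tibble(
    tpr = c(0, cumsum(y) / sum(y)),
    fpr = c(0, cumsum(1 - y) / sum(1 - y))
  )
}

#' @export
autoplot.wf_report <- function(object, ...) {
  se <- object$scored_eval
  rc <- roc_points(se$score, se$label)
  ggplot2::ggplot(rc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(linetype = 2, colour = "grey") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("window-level ROC (AUC %.3f)",
                      mean(object$window_metrics$auc))
    )
}

#' @export
autoplot.wf_ensemble <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$val_loss,
                               colour = factor(.data$member))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "validation loss", colour = "member",
                  title = "ensemble training history")
}
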