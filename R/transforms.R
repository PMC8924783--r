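#' Per-window signal normalization
#'
#' `center_window()` subtracts each axis's within-window mean.
#' `zscore_window()` additionally divides by the within-window population
#' standard deviation (divide by n); axes with zero spread (e.g. watch-off
#' windows) return all zeros rather than non-finite values. Both operate on
#' one window's channel matrix (time x channels) and preserve its shape, and
#' both are idempotent.
#'
#' @param x Numeric matrix, samples in rows, channels in columns.
#' @return Matrix of the same shape.
#' @export
center_window <- function(x) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) abort("non-finite values in window.",
                                class = "wristfork_data_error")
  sweep(x, 2, colMeans(x), "-")
}

#' @rdname center_window
#' @export
zscore_window <- function(x) {
  x <- center_window(x)
  n <- nrow(x)
  sdev <- sqrt(colSums(x^2) / n)
  sdev[sdev < .Machine$double.eps] <- Inf   # constant axis -> zeros
  sweep(x, 2, sdev, "/")
}

#' Random magnitude-scaling augmentation
#'
#' Multiplies every channel of one window by a single scalar drawn uniformly
#' from `range`, emulating between-wear variation in gesture vigor.
#'
#' @param x Window channel matrix (time x channels).
#' @param range Scale interval, lower bound positive (default `c(0.8, 1.2)`).
#' @return The scaled matrix.
#' @export
scale_magnitude <- function(x, range = c(0.8, 1.2)) {
  if (range[1] <= 0 || range[2] < range[1]) {
    abort("`range` must be a positive increasing interval.",
          class = "wristfork_usage_error")
  }
  x * runif(1, range[1], range[2])
}

#' Draw a random 3-D rotation matrix
#'
#' Samples a random point to define an orthonormal frame (equivalently, a
#' uniformly distributed rotation axis), draws an angle from (0, 2*pi), and
#' builds the axis-angle (Rodrigues) rotation matrix. The result `R`
#' satisfies `t(R) %*% R = I` and `det(R) = 1`.
#'
#' @return A 3 x 3 rotation matrix.
#' @export
random_rotation <- function() {
  axis <- rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  theta <- runif(1, 0, 2 * pi)
  rotation_about(axis, theta)
}

#' Axis-angle rotation matrix
#'
#' @param axis Unit 3-vector.
#' @param theta Rotation angle in radians.
#' @return A 3 x 3 rotation matrix.
#' @export
rotation_about <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Rotate the (x, y, z) triples of a window
#'
#' Applies one rotation to every timestep's 3-vector; when the window carries
#' both sensors (6 channels) the same rotation is applied to both triples,
#' since accelerometer and gyroscope share the physical reference frame.
#' This mimics recording the same movement in a differently oriented watch
#' frame.
#'
#' @param x Window channel matrix with 3 or 6 columns (triples of axes).
#' @param rotation A 3 x 3 rotation matrix; drawn by [random_rotation()] when
#'   omitted.
#' @return The rotated matrix.
#' @export
rotate_triples <- function(x, rotation = random_rotation()) {
  x <- as.matrix(x)
  if (ncol(x) %% 3 != 0) {
    abort("channel count must be a multiple of 3 (x, y, z triples).",
          class = "wristfork_usage_error")
  }
  for (b in seq_len(ncol(x) / 3)) {
    cols <- (3 * b - 2):(3 * b)
    x[, cols] <- x[, cols] %*% t(rotation)
  }
  x
}

#' Transform (normalization + augmentation) configuration
#'
#' @param normalization `"centering"` (default, the best-performing choice),
#'   `"zscore"`, or `"none"`.
#' @param scale Apply random magnitude scaling during training.
#' @param scale_range Interval for the scale factor.
#' @param rotation Apply random 3-D rotation during training.
#' @return A `wf_transform_config` list.
#' @export
transform_config <- function(normalization = c("centering", "zscore", "none"),
                             scale = TRUE, scale_range = c(0.8, 1.2),
                             rotation = FALSE) {
  normalization <- match.arg(normalization)
  if (scale_range[1] <= 0 || scale_range[2] < scale_range[1]) {
    abort("`scale_range` lower bound must be positive.",
          class = "wristfork_config_error")
  }
  structure(list(normalization = normalization, scale = scale,
                 scale_range = scale_range, rotation = rotation),
            class = "wf_transform_config")
}

# Normalization applied on both the training and the inference path.
apply_normalization <- function(x, normalization) {
  switch(normalization,
    none = x,
    centering = center_window(x),
    zscore = zscore_window(x)
  )
}

# Stochastic augmentation; training path only.
apply_augmentation <- function(x, cfg) {
  if (isTRUE(cfg$rotation)) x <- rotate_triples(x)
  if (isTRUE(cfg$scale)) x <- scale_magnitude(x, cfg$scale_range)
  x
}
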