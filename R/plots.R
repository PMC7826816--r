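# ggplot2 displays for streams, poses and evaluation objects.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_path
#'   geom_hline facet_wrap labs theme_minimal autoplot scale_x_continuous
#' @export
ggplot2::autoplot

#' Plot sensor-stream channels over time
#'
#' @param object a [sensor_stream()].
#' @param channels channels to show (default: first 6).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sensor_stream <- function(object, channels = NULL, ...) {
  chans <- channels %||% head(stream_channels(object), 6)
  df <- tidyr::pivot_longer(
    as_tibble(object)[c("timestamp_ms", chans)],
    -"timestamp_ms",
    names_to = "channel", values_to = "value"
  )
  ggplot(df, aes(x = .data$timestamp_ms / 1000, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~channel, scales = "free_y", ncol = 1) +
    labs(
      x = "session time (s)", y = NULL,
      title = sprintf("%s stream", stream_modality(object))
    ) +
    theme_minimal()
}

#' Plot a reconstructed skeleton pose
#'
#' Front view (y-z plane of the base frame: y left of the child, z up),
#' joints as points and links as segments.
#'
#' @param object a `skeleton_pose` from [forward_kinematics()].
#' @param model the [body_model()] used (for the link structure).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.skeleton_pose <- function(object, model = default_body_model(), ...) {
  links <- dplyr::filter(model, !is.na(.data$parent)) |>
    left_join(as_tibble(object), by = "joint") |>
    left_join(as_tibble(object),
      by = c(parent = "joint"), suffix = c("", "_p")
    )
  ggplot() +
    ggplot2::geom_segment(
      data = links,
      aes(x = .data$y, y = .data$z, xend = .data$y_p, yend = .data$z_p)
    ) +
    geom_point(data = object, aes(x = .data$y, y = .data$z), size = 2) +
    ggplot2::coord_fixed() +
    labs(x = "y (mm, left)", y = "z (mm, up)", title = "skeleton pose (front view)") +
    theme_minimal()
}

#' Plot per-fold accuracies of a cross-validation result
#'
#' @param object an `escalert_cv`.
#' @param ... unused.
#' @export
autoplot.escalert_cv <- function(object, ...) {
  ggplot(tidy(object), aes(x = factor(.data$fold), y = .data$accuracy)) +
    geom_col() +
    geom_hline(yintercept = object$accuracy, linetype = 2) +
    labs(
      x = "fold", y = "accuracy",
      title = sprintf("%s %d-fold cross-validation", object$algorithm, object$k)
    ) +
    theme_minimal()
}

#' Plot per-subject leave-one-subject-out accuracies
#'
#' @param object an `escalert_loso`.
#' @param ... unused.
#' @export
autoplot.escalert_loso <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$subject_id, y = .data$accuracy)) +
    geom_col() +
    geom_hline(yintercept = object$accuracy, linetype = 2) +
    labs(
      x = "held-out subject", y = "accuracy",
      title = sprintf("%s leave-one-subject-out validation", object$algorithm)
    ) +
    theme_minimal()
}

#' Plot feature or modality importances
#'
#' @param object an `escalert_importance`.
#' @param level `"modality"` (default) or `"feature"`.
#' @param top_n how many features to show at feature level.
#' @param ... unused.
#' @export
autoplot.escalert_importance <- function(object, level = c("modality", "feature"),
                                         top_n = 15, ...) {
  level <- match.arg(level)
  df <- if (level == "modality") {
    rename(object$per_modality, item = "modality")
  } else {
    rename(head(object$per_feature, top_n), item = "feature")
  }
  ggplot(df, aes(x = stats::reorder(.data$item, .data$importance), y = .data$importance)) +
    geom_col() +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "impurity importance (sums to 1 over features)") +
    theme_minimal()
}

#' Plot accuracy against the labeling window
#'
#' @param object an `escalert_windows`.
#' @param ... unused.
#' @export
autoplot.escalert_windows <- function(object, ...) {
  ggplot(object$results, aes(x = .data$window_s, y = .data$accuracy)) +
    geom_line() +
    geom_point() +
    scale_x_continuous(breaks = object$results$window_s) +
    labs(
      x = "labeling window W (s)", y = "accuracy (1:1 oversampled)",
      title = sprintf("%s window sensitivity", object$algorithm)
    ) +
    theme_minimal()
}
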