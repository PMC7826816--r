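# broom-style tidiers for the evaluation objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cross-validation result
#'
#' One row per fold with its accuracy.
#'
#' @param x an `escalert_cv`.
#' @param ... unused.
#' @export
tidy.escalert_cv <- function(x, ...) {
  tibble(
    fold = seq_along(x$fold_accuracies),
    accuracy = x$fold_accuracies,
    algorithm = x$algorithm
  )
}

#' @rdname tidy.escalert_cv
#' @export
glance.escalert_cv <- function(x, ...) {
  bind_cols(
    tibble(
      algorithm = x$algorithm, accuracy = x$accuracy,
      k = x$k, n = x$n, seed = x$seed
    ),
    x$confusion
  )
}

#' Tidy a leave-one-subject-out result
#'
#' One row per held-out subject.
#'
#' @param x an `escalert_loso`.
#' @param ... unused.
#' @export
tidy.escalert_loso <- function(x, ...) {
  dplyr::select(x$per_subject, "subject_id", "accuracy", "n", "flagged")
}

#' @rdname tidy.escalert_loso
#' @export
glance.escalert_loso <- function(x, ...) {
  tibble(
    algorithm = x$algorithm, accuracy = x$accuracy,
    n_subjects = nrow(x$per_subject),
    n_flagged = sum(x$per_subject$flagged), seed = x$seed
  )
}

#' Tidy feature importances
#'
#' @param x an `escalert_importance`.
#' @param ... unused.
#' @export
tidy.escalert_importance <- function(x, ...) {
  mp <- default_modality_map(x$per_feature$feature)
  mutate(x$per_feature, modality = unname(mp[.data$feature]))
}

#' Tidy a window-sensitivity result
#'
#' @param x an `escalert_windows`.
#' @param ... unused.
#' @export
tidy.escalert_windows <- function(x, ...) {
  mutate(x$results, algorithm = x$algorithm)
}
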