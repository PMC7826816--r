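# Classifier families, cross-validation schemes, feature importance and
# the window-sensitivity analysis.
#
# Seven families are supported: random forest (rf), support vector machine
# with RBF kernel (svm), k-nearest neighbours (knn, k = 5), decision tree
# (dt), linear discriminant analysis (da), naive Bayes (nb) and a
# single-hidden-layer neural network (nn, 64 units). Individualized models
# are scored by stratified 5-fold cross-validation; group models by
# leave-one-subject-out validation.

ALGORITHMS <- c("rf", "svm", "knn", "dt", "da", "nb", "nn")

feature_columns <- function(d) {
  setdiff(names(d), c("timestamp_ms", "label", "subject_id", "session_id"))
}

#' Fit one of the seven classifier families
#'
#' @param x numeric feature matrix / data frame.
#' @param y binary labels (0/1).
#' @param algorithm one of `"rf"`, `"svm"`, `"knn"`, `"dt"`, `"da"`,
#'   `"nb"`, `"nn"`.
#' @param seed integer seed (tree bagging, NN initialisation).
#' @param ntree random-forest tree count (default 100).
#' @return an `escalert_fit` object usable with [predict()].
#' @export
fit_classifier <- function(x, y, algorithm = "rf", seed = 1L, ntree = 100) {
  if (!algorithm %in% ALGORITHMS) {
    abort_parameter(sprintf(
      "unknown algorithm '%s'; choose one of %s",
      algorithm, paste(ALGORITHMS, collapse = ", ")
    ))
  }
  x <- as.data.frame(x)
  yf <- factor(y, levels = c(0, 1))
  ctr <- vapply(x, mean, numeric(1))
  scl <- vapply(x, sd, numeric(1))
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- as.data.frame(scale(x, ctr, scl))
  model <- withr::with_seed(seed, switch(algorithm,
    rf = randomForest::randomForest(x, yf, ntree = ntree),
    svm = e1071::svm(xs, yf, kernel = "radial"),
    knn = list(train = xs, y = yf, k = 5L),
    dt = rpart::rpart(label ~ ., data = cbind(x, label = yf), method = "class"),
    da = MASS::lda(x, grouping = yf),
    nb = e1071::naiveBayes(x, yf),
    nn = nnet::nnet(xs, stats::model.matrix(~ yf - 1),
      size = 64, decay = 1e-3, maxit = 100, MaxNWts = 10000,
      trace = FALSE, softmax = TRUE
    )
  ))
  structure(
    list(
      algorithm = algorithm, model = model, center = ctr, scale = scl,
      features = names(x), seed = seed
    ),
    class = "escalert_fit"
  )
}

#' @export
predict.escalert_fit <- function(object, newdata, ...) {
  x <- as.data.frame(newdata)[object$features]
  xs <- as.data.frame(scale(x, object$center, object$scale))
  m <- object$model
  out <- switch(object$algorithm,
    rf = predict(m, x),
    svm = predict(m, xs),
    knn = class::knn(m$train, xs, m$y, k = m$k),
    dt = predict(m, x, type = "class"),
    da = predict(m, x)$class,
    nb = predict(m, x),
    nn = factor(c("0", "1")[max.col(predict(m, xs))], levels = c("0", "1"))
  )
  as.integer(as.character(out))
}

# seeded stratified fold assignment: within each class, shuffle then deal
# round-robin, so every fold has both classes in near-original proportion
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

confusion_counts <- function(truth, pred) {
  tibble(
    tp = sum(truth == 1 & pred == 1), fp = sum(truth == 0 & pred == 1),
    fn = sum(truth == 1 & pred == 0), tn = sum(truth == 0 & pred == 0)
  )
}

#' Stratified k-fold cross-validation of an individualized model
#'
#' @param d a `labeled_dataset` with both classes present.
#' @param algorithm classifier family (see [fit_classifier()]).
#' @param k number of folds (default 5).
#' @param seed integer seed controlling folds and fits.
#' @param ... passed to [fit_classifier()].
#' @return an `escalert_cv` object: mean accuracy over folds, per-fold
#'   accuracies, and the pooled out-of-fold confusion matrix. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
crossval_individual <- function(d, algorithm = "rf", k = 5, seed = 1L, ...) {
  if (length(unique(d$label)) < 2L) abort_parameter("both classes must be present")
  feats <- feature_columns(d)
  x <- as.data.frame(d)[feats]
  y <- d$label
  folds <- stratified_folds(y, k, seed)
  pred <- integer(length(y))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- fit_classifier(x[!test, , drop = FALSE], y[!test], algorithm,
      seed = seed + f, ...
    )
    pred[test] <- predict(fit, x[test, , drop = FALSE])
    fold_acc[f] <- mean(pred[test] == y[test])
  }
  structure(
    list(
      algorithm = algorithm, k = k, seed = seed,
      accuracy = mean(fold_acc), fold_accuracies = fold_acc,
      confusion = confusion_counts(y, pred), n = length(y),
      subject_id = attr(d, "subject_id")
    ),
    class = "escalert_cv"
  )
}

#' @export
print.escalert_cv <- function(x, ...) {
  cat(sprintf(
    "<escalert_cv> %s, %d-fold: accuracy %.4f (folds %s)\n",
    x$algorithm, x$k, x$accuracy,
    paste(sprintf("%.3f", x$fold_accuracies), collapse = " ")
  ))
  invisible(x)
}

#' Single 80/20 stratified holdout evaluation
#'
#' A companion to [crossval_individual()]: one stratified split, one fit,
#' one confusion matrix on the held-out 20%.
#'
#' @inheritParams crossval_individual
#' @param test_prop held-out proportion (default 0.2).
#' @return an `escalert_cv`-like object with `accuracy` and `confusion`.
#' @export
holdout_individual <- function(d, algorithm = "rf", test_prop = 0.2,
                               seed = 1L, ...) {
  feats <- feature_columns(d)
  x <- as.data.frame(d)[feats]
  y <- d$label
  test <- logical(length(y))
  withr::with_seed(seed, for (cl in unique(y)) {
    idx <- which(y == cl)
    test[sample(idx, round(test_prop * length(idx)))] <- TRUE
  })
  fit <- fit_classifier(x[!test, , drop = FALSE], y[!test], algorithm,
    seed = seed, ...
  )
  pred <- predict(fit, x[test, , drop = FALSE])
  structure(
    list(
      algorithm = algorithm, k = 1L, seed = seed,
      accuracy = mean(pred == y[test]), fold_accuracies = mean(pred == y[test]),
      confusion = confusion_counts(y[test], pred), n = sum(test),
      subject_id = attr(d, "subject_id")
    ),
    class = "escalert_cv"
  )
}

#' Leave-one-subject-out group validation
#'
#' For each subject, a model is trained on the pooled data of all other
#' subjects and tested on the held-out subject — the group-model scheme.
#' Subjects whose data contain a single class are flagged and skipped.
#'
#' @param datasets named list of per-subject `labeled_dataset`s (at
#'   least 2).
#' @param algorithm classifier family.
#' @param seed integer seed.
#' @param ... passed to [fit_classifier()].
#' @return an `escalert_loso` object with per-subject accuracies and
#'   confusions and their mean. Supports `tidy()` / `glance()`.
#' @export
loso_group <- function(datasets, algorithm = "rf", seed = 1L, ...) {
  if (length(datasets) < 2L) abort_parameter("need at least 2 subjects")
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    names(datasets) <- paste0("S", seq_along(datasets))
  }
  feats <- Reduce(intersect, purrr::map(datasets, feature_columns))
  rows <- purrr::imap(datasets, function(d, id) {
    flagged <- length(unique(d$label)) < 2L
    if (flagged) {
      return(tibble(
        subject_id = id, accuracy = NA_real_, n = nrow(d),
        flagged = TRUE, confusion = list(NULL)
      ))
    }
    train <- purrr::list_rbind(purrr::map(
      datasets[setdiff(names(datasets), id)],
      function(dd) as_tibble(dd)[c(feats, "label")]
    ))
    fit <- fit_classifier(train[feats], train$label, algorithm, seed = seed, ...)
    pred <- predict(fit, as.data.frame(d)[feats])
    tibble(
      subject_id = id, accuracy = mean(pred == d$label), n = nrow(d),
      flagged = FALSE, confusion = list(confusion_counts(d$label, pred))
    )
  }) |> list_rbind()
  structure(
    list(
      algorithm = algorithm, seed = seed, per_subject = rows,
      accuracy = mean(rows$accuracy, na.rm = TRUE)
    ),
    class = "escalert_loso"
  )
}

#' @export
print.escalert_loso <- function(x, ...) {
  cat(sprintf(
    "<escalert_loso> %s: mean accuracy %.4f over %d subjects\n",
    x$algorithm, x$accuracy, nrow(x$per_subject)
  ))
  invisible(x)
}

#' Modality grouping of the default feature set
#'
#' Maps feature names to the five reporting groups: body motion, wrist
#' physiology (HR + EDA), wrist acceleration, head rotations, facial
#' expressions.
#'
#' @param features character vector of feature names.
#' @return named character vector `feature -> modality`.
#' @export
default_modality_map <- function(features) {
  mod <- dplyr::case_when(
    grepl("^(lfa|rfa|lua|rua|torso)_", features) ~ "body_motion",
    features %in% c("hr_bpm", "scl_us", "scr_us") ~ "physiology",
    grepl("^wrist_", features) ~ "wrist_acceleration",
    grepl("^head_", features) ~ "head_rotations",
    grepl("^face_", features) ~ "facial_expressions",
    TRUE ~ "other"
  )
  rlang::set_names(mod, features)
}

#' Impurity-based feature and modality importances
#'
#' Random-forest importances are the total decrease in node impurity from
#' splitting on each feature, averaged over trees and normalized so all
#' features sum to 1; modality importances are sums over member features.
#'
#' @param object a `labeled_dataset` (a forest is fitted with `seed`,
#'   `ntree`) or an `escalert_fit` with `algorithm = "rf"`.
#' @param grouping named `feature -> modality` map (default
#'   [default_modality_map()]).
#' @param seed,ntree forest fitting parameters when `object` is a dataset.
#' @return an `escalert_importance` object with tibbles `per_feature`
#'   (descending importance) and `per_modality`.
#' @export
feature_importance <- function(object, grouping = NULL, seed = 1L, ntree = 100) {
  if (inherits(object, "escalert_fit")) {
    if (object$algorithm != "rf") {
      abort_parameter("impurity importances require a random-forest model")
    }
    fit <- object
  } else {
    feats <- feature_columns(object)
    fit <- fit_classifier(as.data.frame(object)[feats], object$label, "rf",
      seed = seed, ntree = ntree
    )
  }
  imp <- randomForest::importance(fit$model, type = 2)[, 1]
  imp <- imp / sum(imp)
  per_feature <- tibble(feature = names(imp), importance = unname(imp)) |>
    arrange(dplyr::desc(.data$importance))
  if (is.null(grouping)) grouping <- default_modality_map(per_feature$feature)
  per_modality <- per_feature |>
    mutate(modality = unname(grouping[.data$feature])) |>
    group_by(.data$modality) |>
    summarise(importance = sum(.data$importance), .groups = "drop") |>
    arrange(dplyr::desc(.data$importance))
  structure(
    list(per_feature = per_feature, per_modality = per_modality),
    class = "escalert_importance"
  )
}

#' @export
print.escalert_importance <- function(x, ...) {
  cat("<escalert_importance> top features:\n")
  print(head(x$per_feature, 5))
  cat("modalities:\n")
  print(x$per_modality)
  invisible(x)
}

#' Sensitivity of prediction accuracy to the labeling window
#'
#' Relabels the feature timeline at each window W, oversamples the
#' minority class to a 1:1 ratio, and scores the classifier by stratified
#' k-fold cross-validation — one accuracy per window.
#'
#' @param fm a `feature_matrix`.
#' @param log an [event_log()] (or precursor timestamp vector) on the same
#'   session clock.
#' @param windows windows in seconds (default `c(30, 60, 90, 120)`).
#' @param algorithm classifier family (default `"rf"`).
#' @param k folds (default 5).
#' @param seed integer seed.
#' @param ... passed to [fit_classifier()].
#' @return an `escalert_windows` object: tibble with `window_s`,
#'   `accuracy`, `n`, plus settings.
#' @export
window_sensitivity <- function(fm, log, windows = c(30, 60, 90, 120),
                               algorithm = "rf", k = 5, seed = 1L, ...) {
  if (any(windows <= 0)) abort_parameter("windows must be > 0")
  rows <- purrr::map(windows, function(w) {
    d <- assign_labels(fm, log, window_s = w)
    d <- oversample_minority(d, seed = seed)
    cv <- crossval_individual(d, algorithm, k = k, seed = seed, ...)
    tibble(window_s = w, accuracy = cv$accuracy, n = cv$n)
  }) |> list_rbind()
  structure(
    list(results = rows, algorithm = algorithm, k = k, seed = seed),
    class = "escalert_windows"
  )
}

#' @export
print.escalert_windows <- function(x, ...) {
  cat(sprintf("<escalert_windows> %s, %d-fold:\n", x$algorithm, x$k))
  print(x$results)
  invisible(x)
}
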