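# a small separable two-class dataset builder: class 1 shifts the first
# `informative` features by `delta`, everything else is noise
make_dataset <- function(n = 300, p = 6, informative = 1, delta = 3,
                         frac1 = 0.4, seed = 1) {
  withr::with_seed(seed, {
    y <- rbinom(n, 1, frac1)
    x <- matrix(rnorm(n * p), n)
    for (j in seq_len(informative)) x[, j] <- x[, j] + delta * y
    colnames(x) <- paste0("f", seq_len(p))
    structure(
      dplyr::bind_cols(
        tibble::tibble(timestamp_ms = seq_len(n) * 66),
        tibble::as_tibble(x), tibble::tibble(label = y)
      ),
      class = c("labeled_dataset", class(tibble::tibble()))
    )
  })
}

test_that("cross-validation separates a separable dataset and is deterministic", {
  d <- make_dataset(n = 400, delta = 4)
  cv <- crossval_individual(d, "rf", seed = 1)
  expect_gte(cv$accuracy, 0.95)
  expect_length(cv$fold_accuracies, 5L)
  with(cv$confusion, expect_equal(tp + fp + fn + tn, nrow(d)))
  expect_identical(crossval_individual(d, "rf", seed = 1), cv)
  expect_false(identical(crossval_individual(d, "rf", seed = 2)$accuracy, cv$accuracy))
  expect_error(crossval_individual(d, "boost"), class = "escalert_parameter_error")
  expect_error(
    crossval_individual(dplyr::filter(d, label == 1), "rf"),
    class = "escalert_parameter_error"
  )
})

test_that("permuted labels on a balanced dataset score at chance", {
  d <- make_dataset(n = 600, delta = 3, frac1 = 0.5, seed = 3)
  d$label <- withr::with_seed(11, sample(d$label))
  cv <- crossval_individual(d, "rf", seed = 1)
  expect_lt(abs(cv$accuracy - 0.5), 0.06)
})

test_that("all seven algorithm families run end-to-end", {
  d <- make_dataset(n = 240, delta = 4, seed = 5)
  for (algo in c("rf", "svm", "knn", "dt", "da", "nb", "nn")) {
    cv <- crossval_individual(d, algo, seed = 1)
    expect_gt(cv$accuracy, 0.8) # separable by construction
    expect_identical(crossval_individual(d, algo, seed = 1)$accuracy, cv$accuracy)
  }
})

test_that("tidy/glance expose fold accuracies and pooled confusion", {
  d <- make_dataset()
  cv <- crossval_individual(d, "dt", seed = 2)
  td <- tidy(cv)
  expect_equal(nrow(td), 5L)
  expect_equal(mean(td$accuracy), cv$accuracy)
  g <- glance(cv)
  expect_equal(g$accuracy, cv$accuracy)
  expect_equal(g$tp + g$fp + g$fn + g$tn, nrow(d))
})

test_that("leave-one-subject-out holds each subject fully out of training", {
  # identically distributed subjects: LOSO close to individualized
  homog <- purrr::map(1:3, function(i) make_dataset(n = 300, seed = 20 + i))
  names(homog) <- paste0("S", 1:3)
  lo <- loso_group(homog, "rf", seed = 1)
  expect_equal(nrow(lo$per_subject), 3L)
  ind <- mean(purrr::map_dbl(homog, function(d) {
    crossval_individual(d, "rf", seed = 1)$accuracy
  }))
  expect_lt(abs(lo$accuracy - ind), 0.05)

  # subject-specific signatures: LOSO strictly below individualized.
  # class 1 shifts a different feature per subject, so cross-subject
  # patterns do not transfer
  heterog <- purrr::map(1:3, function(i) {
    d <- make_dataset(n = 300, p = 6, informative = 0, seed = 30 + i)
    d[[paste0("f", i)]] <- d[[paste0("f", i)]] + 4 * d$label
    d
  })
  names(heterog) <- paste0("S", 1:3)
  lo_h <- loso_group(heterog, "rf", seed = 1)
  ind_h <- mean(purrr::map_dbl(heterog, function(d) {
    crossval_individual(d, "rf", seed = 1)$accuracy
  }))
  expect_lt(lo_h$accuracy, ind_h)

  # single-class subject is flagged, not fitted
  degenerate <- c(homog[1:2], list(S3 = dplyr::filter(homog[[3]], label == 0)))
  lo_d <- loso_group(degenerate, "dt", seed = 1)
  expect_true(lo_d$per_subject$flagged[3])
  expect_true(is.na(lo_d$per_subject$accuracy[3]))

  expect_error(loso_group(homog[1], "rf"), class = "escalert_parameter_error")
})

test_that("a planted single-feature signal tops the importance ranking", {
  d <- make_dataset(n = 500, p = 8, informative = 1, delta = 4, seed = 9)
  imp <- feature_importance(d, seed = 1)
  expect_equal(imp$per_feature$feature[1], "f1")
  expect_equal(sum(imp$per_feature$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$per_feature$importance >= 0))
  # modality sums equal brute-force addition over member features
  mp <- rlang::set_names(
    rep(c("modA", "modB"), each = 4),
    paste0("f", 1:8)
  )
  imp2 <- feature_importance(d, grouping = mp, seed = 1)
  manual <- tapply(
    imp2$per_feature$importance,
    mp[imp2$per_feature$feature], sum
  )
  got <- rlang::set_names(imp2$per_modality$importance, imp2$per_modality$modality)
  expect_equal(got[names(manual)], manual, tolerance = 1e-12, ignore_attr = TRUE)
  # non-forest fits are unsupported
  fit <- fit_classifier(d[paste0("f", 1:8)], d$label, "dt")
  expect_error(feature_importance(fit), class = "escalert_parameter_error")
})

test_that("window sensitivity rebalances to exactly 1:1 at every window", {
  set.seed(2)
  ts <- seq(0, 400000, by = 2000)
  fm <- tibble::tibble(timestamp_ms = ts, x = rnorm(length(ts)))
  events <- c(120000, 300000)
  fm$x <- fm$x + 2 * assign_labels(fm, events, window_s = 60)$label
  ws <- window_sensitivity(fm, events,
    windows = c(30, 60), algorithm = "dt", k = 3, seed = 1
  )
  for (i in seq_len(nrow(ws$results))) {
    w <- ws$results$window_s[i]
    n1 <- sum(assign_labels(fm, events, window_s = w)$label)
    n0 <- length(ts) - n1
    expect_equal(ws$results$n[i], 2L * max(n0, n1))
  }
  expect_error(window_sensitivity(fm, events, windows = c(-30, 60)),
    class = "escalert_parameter_error"
  )
})

test_that("the 80/20 holdout reports a confusion matrix on the held-out fifth", {
  d <- make_dataset(n = 500, delta = 4, seed = 13)
  h <- holdout_individual(d, "rf", seed = 1)
  expect_equal(h$n, 100L)
  with(h$confusion, expect_equal(tp + fp + fn + tn, 100L))
  expect_gte(h$accuracy, 0.9)
})
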