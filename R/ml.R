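#' Train a classical-ML baseline on raw pixel rows
#'
#' Fits one of the four comparison classifiers to the 64 raw pixel
#' columns of a labeled dataset (deliberately without interpolation —
#' the upsampling step belongs to the closed-form detector only):
#'
#' * `"knn"` — k-nearest neighbours with Euclidean distance (default
#'   `k = 5`); an instance-based method, so the "model" stores the
#'   training rows.
#' * `"svm"` — support vector machine, RBF kernel, regularization cost 1
#'   by default ([e1071::svm()]).
#' * `"rf"` — random forest of 100 trees by default
#'   ([randomForest::randomForest()]).
#' * `"nb"` — Gaussian naive Bayes ([e1071::naiveBayes()]).
#'
#' @param algorithm one of `"knn"`, `"svm"`, `"rf"`, `"nb"`.
#' @param train labeled dataset with pixel columns `p00`..`p63` and a
#'   `state` column; must contain at least two classes.
#' @param k neighbours for knn (> 0).
#' @param cost SVM regularization weight (> 0).
#' @param ntree random-forest tree count (> 0).
#' @param seed integer seed controlling any randomness in fitting
#'   (bootstrap draws, tie-breaking).
#' @return An object of class `thermal_classifier` with a
#'   [predict][predict.thermal_classifier] method.
#' @export
train_classifier <- function(algorithm = c("knn", "svm", "rf", "nb"),
                             train, k = 5, cost = 1, ntree = 100,
                             seed = 42) {
  algorithm <- match.arg(algorithm)
  stopifnot(k > 0, cost > 0, ntree > 0)
  check_dataset_schema(train)
  y <- factor(train$state)
  if (nlevels(y) < 2L) {
    stop("training set has a single class; nothing to discriminate",
         call. = FALSE)
  }
  if (any(table(y) < 1L)) stop("every class needs at least one row",
                               call. = FALSE)
  x <- as.matrix(train[, sprintf("p%02d", 0:63)])
  elapsed <- system.time(
    fit <- with_scene_seed(seed, switch(algorithm,
      knn = list(x = x, y = y, k = as.integer(k)),
      svm = e1071::svm(x, y, kernel = "radial", cost = cost),
      rf  = randomForest::randomForest(x, y, ntree = as.integer(ntree)),
      nb  = e1071::naiveBayes(x, y)
    ))
  )[["elapsed"]]
  structure(
    list(algorithm = algorithm, fit = fit, levels = levels(y),
         n_train = nrow(x), seed = seed, train_time = elapsed),
    class = "thermal_classifier"
  )
}

#' Predict states for new pixel rows
#'
#' @param object a [train_classifier()] fit.
#' @param newdata data frame with pixel columns `p00`..`p63`.
#' @param ... unused.
#' @return Factor of predicted state labels.
#' @export
predict.thermal_classifier <- function(object, newdata, ...) {
  pcols <- sprintf("p%02d", 0:63)
  if (!all(pcols %in% names(newdata))) {
    stop("schema error: newdata lacks pixel columns p00..p63",
         call. = FALSE)
  }
  x <- as.matrix(newdata[, pcols])
  with_scene_seed(object$seed, switch(object$algorithm,
    knn = class::knn(object$fit$x, x, object$fit$y, k = object$fit$k),
    svm = stats::predict(object$fit, x),
    rf  = stats::predict(object$fit, x),
    nb  = stats::predict(object$fit, x)
  ))
}

#' @export
print.thermal_classifier <- function(x, ...) {
  cat("<thermal_classifier> ", x$algorithm, ", ", length(x$levels),
      " states (", paste(x$levels, collapse = ", "), "), ",
      x$n_train, " training rows\n", sep = "")
  invisible(x)
}

#' Evaluate a classifier on a held-out test set
#'
#' Computes overall and per-state accuracies (percent of test rows whose
#' predicted state matches the label column) and the confusion matrix.
#' Per-state accuracy is the fraction of that state's test rows labeled
#' correctly, so confusion-matrix row sums equal the per-state test
#' counts. Wall-clock prediction time is recorded for interest only.
#'
#' @param model a [train_classifier()] fit.
#' @param test labeled test dataset in the canonical schema; must be
#'   non-empty.
#' @return An object of class `eval_report`: a list with `algorithm`,
#'   `overall_accuracy` and `per_state_accuracy` (percentages in
#'   \[0, 100\]), `confusion` (true state x predicted state), `n_train`,
#'   `n_test`, `train_time`, `predict_time`.
#' @export
evaluate_classifier <- function(model, test) {
  stopifnot(inherits(model, "thermal_classifier"))
  check_dataset_schema(test)
  if (nrow(test) == 0L) stop("empty test set", call. = FALSE)
  truth <- factor(test$state, levels = union(model$levels,
                                             unique(test$state)))
  elapsed <- system.time(
    pred <- factor(as.character(predict(model, test)),
                   levels = levels(truth))
  )[["elapsed"]]
  confusion <- table(truth = truth, predicted = pred)
  per_state <- vapply(levels(truth), function(s) {
    n <- sum(truth == s)
    if (n == 0) NA_real_ else 100 * sum(truth == s & pred == s) / n
  }, numeric(1))
  structure(
    list(algorithm = model$algorithm,
         overall_accuracy = 100 * mean(pred == truth),
         per_state_accuracy = per_state,
         confusion = confusion,
         n_train = model$n_train, n_test = nrow(test),
         train_time = model$train_time, predict_time = elapsed),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, digits = 1, ...) {
  cat("<eval_report> ", x$algorithm, ": overall accuracy ",
      formatC(x$overall_accuracy, digits = digits, format = "f"),
      "% (", x$n_train, " train / ", x$n_test, " test rows)\n", sep = "")
  acc <- x$per_state_accuracy[!is.na(x$per_state_accuracy)]
  cat("  per state: ",
      paste(sprintf("%s %.1f%%", names(acc), acc), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Compare all baselines on one shared split
#'
#' Splits the dataset once, trains every requested algorithm on the same
#' training rows and evaluates on the same test rows, and tabulates
#' per-state and overall accuracies — one row per algorithm, one column
#' per state.
#'
#' @param dataset labeled dataset in the canonical schema.
#' @param algorithms algorithms to compare.
#' @param test_fraction,seed passed to [split_dataset()]; `seed` also
#'   seeds every fit.
#' @param ... hyperparameters forwarded to [train_classifier()].
#' @return A data frame with columns `algorithm`, one accuracy column per
#'   state (percent), and `overall`; the per-algorithm `eval_report`s are
#'   attached as the `reports` attribute.
#' @export
compare_classifiers <- function(dataset,
                                algorithms = c("knn", "svm", "rf", "nb"),
                                test_fraction = 0.2, seed = 42, ...) {
  sp <- split_dataset(dataset, test_fraction = test_fraction, seed = seed)
  reports <- lapply(algorithms, function(alg) {
    fit <- train_classifier(alg, sp$train, seed = seed, ...)
    evaluate_classifier(fit, sp$test)
  })
  names(reports) <- algorithms
  states <- sort(unique(as.character(dataset$state)))
  tab <- data.frame(algorithm = algorithms, stringsAsFactors = FALSE)
  for (s in states) {
    tab[[s]] <- vapply(reports, function(r) r$per_state_accuracy[[s]],
                       numeric(1))
  }
  tab$overall <- vapply(reports, `[[`, numeric(1), "overall_accuracy")
  attr(tab, "reports") <- reports
  tab
}
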