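# Evaluation: leave-one-trial-out CV, ablation, majority voting, grouped
# simulated real-time protocol, correlation.

#' Confusion matrix
#'
#' @param true,pred Label vectors of equal length.
#' @param labels Label universe fixing row/column order (default: the labels
#'   present, in [movement_labels()] order when applicable).
#' @return A `confusion_matrix`: integer `K x K` matrix (rows = true,
#'   columns = predicted) with attributes `accuracy` (trace/total) and
#'   `recall` (per-class).
#' @export
confusion_matrix <- function(true, pred, labels = NULL) {
  true <- as.character(true); pred <- as.character(pred)
  if (is.null(labels)) {
    labels <- unique(c(true, pred))
    if (all(labels %in% movement_labels())) {
      labels <- movement_labels()[movement_labels() %in% labels]
    } else labels <- sort(labels)
  }
  m <- table(factor(true, levels = labels), factor(pred, levels = labels))
  m <- unclass(as.matrix(m))
  names(dimnames(m)) <- c("true", "predicted")
  acc <- sum(diag(m)) / sum(m)
  rec <- diag(m) / pmax(rowSums(m), 1)
  structure(m, accuracy = acc, recall = rec, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion matrix (rows = true), accuracy =",
      sprintf("%.3f", attr(x, "accuracy")), "\n")
  print(unclass(x))
  invisible(x)
}

#' Overall accuracy of a confusion matrix
#' @param cm A `confusion_matrix`.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(cm) attr(cm, "accuracy")

fit_any <- function(model, x, y, lambda, seed) {
  if (identical(toupper(model), "LDA")) {
    fit_lda(x, y, lambda = lambda)
  } else {
    fit_comparator(comparator_spec(model), x, y, seed = seed)
  }
}

predict_any <- function(fit, x) {
  if (inherits(fit, "lda_model")) predict_lda(fit, x)$label
  else predict_comparator(fit, x)
}

#' Leave-one-trial-out cross-validation
#'
#' Each trial is held out in turn: a model is trained on all other trials'
#' frames and tested on the held-out trial's frames. The CV unit is always
#' the trial, never the frame — overlapping windows within a trial would
#' otherwise leak between train and test. Frames are normalized per trial
#' ([zscore_by_trial()]) before splitting (each trial's statistics involve
#' only that trial), invalid frames are excluded, and a structural assertion
#' verifies that no test frame index appears in its fold's training set.
#'
#' @param fm A raw (unnormalized) `feature_matrix` spanning >= 2 trials,
#'   e.g. from [rbind_features()] over one subject's trials.
#' @param model `"lda"` (default) or a comparator kind
#'   (`"dt"/"knn"/"rf"/"svm"`).
#' @param sensors Sensor subset (default all three).
#' @param lambda LDA shrinkage.
#' @param seed Seed for stochastic learners.
#' @return List: `confusion` (aggregated over folds), `accuracy` (mean of
#'   per-fold accuracies), `fold_accuracy`, `n_folds`, `sensors`, `model`.
#' @export
loto_cv <- function(fm, model = "lda", sensors = c("EMG", "FMG", "IMU"),
                    lambda = 1e-3, seed = 1L) {
  trials <- sort(unique(fm$trial_id))
  if (length(trials) < 2) stop("loto_cv: need >= 2 trials", call. = FALSE)
  fmz <- zscore_by_trial(fm)
  keep <- fmz$valid
  mask <- sensor_mask(sensors)
  x <- fmz$x[keep, mask, drop = FALSE]
  y <- fmz$label[keep]
  trial <- fmz$trial_id[keep]
  labels <- unique(y)
  true_all <- character(0); pred_all <- character(0)
  fold_acc <- numeric(length(trials))
  for (fi in seq_along(trials)) {
    te <- which(trial == trials[fi])
    tr <- which(trial != trials[fi])
    stopifnot(length(intersect(te, tr)) == 0)  # no leakage, ever
    miss <- setdiff(labels, unique(y[tr]))
    if (length(miss) > 0) {
      stop("label(s) missing from training fold ", trials[fi], ": ",
           paste(miss, collapse = ","), call. = FALSE)
    }
    fit <- fit_any(model, x[tr, , drop = FALSE], y[tr], lambda, seed)
    pred <- predict_any(fit, x[te, , drop = FALSE])
    fold_acc[fi] <- mean(pred == y[te])
    true_all <- c(true_all, y[te]); pred_all <- c(pred_all, pred)
  }
  cm <- confusion_matrix(true_all, pred_all)
  list(confusion = cm, accuracy = mean(fold_acc), fold_accuracy = fold_acc,
       n_folds = length(trials), sensors = sensors, model = model)
}

#' Sensor-configuration ablation
#'
#' Runs [loto_cv()] under each of the 7 non-empty subsets of
#' `{EMG, FMG, IMU}` by masking columns of the same extracted features (no
#' re-extraction).
#'
#' @inheritParams loto_cv
#' @return Data frame with one row per configuration: `sensors`,
#'   `n_features`, `accuracy`; per-config results as attribute `"runs"`.
#' @export
ablate_sensors <- function(fm, model = "lda", lambda = 1e-3, seed = 1L) {
  cfgs <- sensor_configs()
  runs <- lapply(cfgs, function(s) {
    loto_cv(fm, model = model, sensors = s, lambda = lambda, seed = seed)
  })
  out <- data.frame(
    sensors = names(cfgs),
    n_features = vapply(cfgs, function(s) length(sensor_mask(s)), integer(1)),
    accuracy = vapply(runs, `[[`, numeric(1), "accuracy"),
    row.names = NULL
  )
  attr(out, "runs") <- runs
  out
}

#' Majority vote over a window of frame predictions
#'
#' Returns the most frequent label among valid frames. Ties are broken by
#' the highest summed discriminant score over the tied labels when `scores`
#' are supplied, else by the lowest class index — deterministic either way.
#'
#' @param labels Character vector of frame predictions.
#' @param scores Optional `[n x K]` discriminant-score matrix with class
#'   column names (e.g. from [predict_lda()]).
#' @param valid Optional logical vector; `FALSE` frames are excluded.
#' @return The voted label (length-1 character).
#' @export
majority_vote <- function(labels, scores = NULL, valid = NULL) {
  if (length(labels) == 0) stop("majority_vote: no predictions",
                                call. = FALSE)
  if (!is.null(valid)) {
    if (!any(valid)) stop("majority_vote: no valid frames", call. = FALSE)
    labels <- labels[valid]
    if (!is.null(scores)) scores <- scores[valid, , drop = FALSE]
  }
  tab <- table(labels)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1) return(winners)
  if (!is.null(scores)) {
    tot <- vapply(winners, function(l) {
      sum(scores[labels == l, l])
    }, numeric(1))
    return(winners[which.max(tot)])
  }
  ord <- match(winners, movement_labels())
  if (any(is.na(ord))) winners[1] else winners[which.min(ord)]
}

#' Pearson correlation with a t-test p-value
#'
#' Thin wrapper over [stats::cor.test()] for the correlation analyses
#' (accuracy-vs-accuracy, accuracy-vs-impairment).
#'
#' @param a,b Numeric vectors, equal length >= 3, non-constant.
#' @param alternative Passed to `cor.test` (default two-sided).
#' @return `list(r, p, n)`.
#' @export
pearson_corr <- function(a, b, alternative = "two.sided") {
  if (length(a) != length(b) || length(a) < 3) {
    stop("pearson_corr: need equal-length vectors of >= 3 values",
         call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("pearson_corr: constant input vector", call. = FALSE)
  }
  ct <- stats::cor.test(a, b, method = "pearson",
                        alternative = alternative)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}
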