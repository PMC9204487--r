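# Comparison classifiers at fixed hyperparameters
# -----------------------------------------------
# Baselines, not the contribution: library-backed behind a uniform
# fit/predict interface. Frozen settings: DT = entropy split (unpruned);
# KNN = 3 neighbors, Euclidean; RF = 40 trees, minimum leaf size 1;
# SVM = linear kernel, C = 100.

#' Comparator specification
#'
#' @param kind One of `"DT"`, `"KNN"`, `"RF"`, `"SVM"` (case-insensitive).
#' @param ... Optional overrides of the frozen hyperparameters.
#' @return A `comparator_spec`.
#' @export
comparator_spec <- function(kind, ...) {
  kind <- toupper(kind)
  params <- switch(kind,
    DT  = list(split = "information"),
    KNN = list(k = 3L),
    RF  = list(ntree = 40L, nodesize = 1L),
    SVM = list(kernel = "linear", cost = 100),
    stop("unknown comparator kind: ", kind, call. = FALSE)
  )
  over <- list(...)
  params[names(over)] <- over
  structure(list(kind = kind, params = params), class = "comparator_spec")
}

#' Fit a comparison classifier
#'
#' @param spec A [comparator_spec()].
#' @param x Feature matrix `[n x p]`.
#' @param y Class labels.
#' @param seed Optional seed for the stochastic learners (RF); makes
#'   refitting reproducible.
#' @return A `comparator_model` with a uniform [predict_comparator()]
#'   interface.
#' @export
fit_comparator <- function(spec, x, y, seed = NULL) {
  x <- as.matrix(x)
  y <- factor(as.character(y))
  fit <- switch(spec$kind,
    DT = {
      df <- as.data.frame(x)
      names(df) <- paste0("f", seq_len(ncol(x)))
      df$.y <- y
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(split = spec$params$split),
                   control = rpart::rpart.control(minsplit = 2L,
                                                  minbucket = 1L,
                                                  cp = 0, xval = 0L))
    },
    KNN = list(train = x, cl = y, k = spec$params$k),
    RF = {
      if (!is.null(seed)) set.seed(seed)
      randomForest::randomForest(x, y, ntree = spec$params$ntree,
                                 nodesize = spec$params$nodesize)
    },
    SVM = e1071::svm(x, y, kernel = spec$params$kernel,
                     cost = spec$params$cost, scale = FALSE)
  )
  structure(list(kind = spec$kind, fit = fit, levels = levels(y)),
            class = "comparator_model")
}

#' Predict with a comparison classifier
#'
#' @param model A `comparator_model`.
#' @param x Feature matrix (or single-frame vector).
#' @return Character vector of predicted labels.
#' @export
predict_comparator <- function(model, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  switch(model$kind,
    DT = {
      df <- as.data.frame(x)
      names(df) <- paste0("f", seq_len(ncol(x)))
      as.character(predict(model$fit, df, type = "class"))
    },
    KNN = as.character(class::knn(model$fit$train, x, model$fit$cl,
                                  k = model$fit$k)),
    RF = {
      # predict(..., type = "response") breaks vote ties at random; argmax
      # over the vote matrix with a first-index tie-break is deterministic
      votes <- predict(model$fit, x, type = "vote")
      colnames(votes)[max.col(votes, ties.method = "first")]
    },
    SVM = as.character(predict(model$fit, x))
  )
}

#' Random-forest Gini feature importance ranking
#'
#' Fits the frozen RF specification (40 trees, leaf size 1) and ranks
#' features by mean decrease in Gini impurity, normalized to sum to one over
#' all features before truncation to the top `top_k`. Each ranked feature is
#' tagged with its sensing modality (EMG/FMG/IMU) from the frozen column
#' layout.
#'
#' @param x Feature matrix (68 columns, or a masked subset with
#'   `col_index` giving original column indices).
#' @param y Class labels.
#' @param seed Seed for the forest.
#' @param top_k Entries to keep (default 10).
#' @param col_index Original fused-vector indices of `x`'s columns.
#' @return Data frame `rank, index, feature, modality, importance` (top-k,
#'   decreasing), with the full normalized importance vector as attribute
#'   `"all_importances"`.
#' @export
gini_importance <- function(x, y, seed = 1L, top_k = 10L,
                            col_index = seq_len(ncol(x))) {
  x <- as.matrix(x)
  set.seed(seed)
  rf <- randomForest::randomForest(x, factor(as.character(y)),
                                   ntree = 40L, nodesize = 1L)
  imp <- rf$importance[, "MeanDecreaseGini"]
  imp <- imp / sum(imp)
  ord <- order(imp, decreasing = TRUE)
  top <- utils::head(ord, top_k)
  out <- data.frame(
    rank = seq_along(top),
    index = col_index[top],
    feature = feature_names()[col_index[top]],
    modality = feature_modality(col_index[top]),
    importance = unname(imp[top])
  )
  attr(out, "all_importances") <- unname(imp)
  out
}
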