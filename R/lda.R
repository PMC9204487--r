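# Linear discriminant analysis, implemented from its discriminant function
# ------------------------------------------------------------------------
# Under the equal-covariance Gaussian model, the class-k discriminant is
#     delta_k(x) = x' S^{-1} mu_k - 1/2 mu_k' S^{-1} mu_k + log pi_k
# with mu_k the class mean, S the pooled within-class covariance and pi_k
# the prior. The predicted class is argmax_k delta_k(x). S is shrunk as
# (1 - lambda) S + lambda diag(S): with 68 features and ~60 frames per
# movement per trial the pooled estimate is near-singular, and a small
# diagonal shrinkage keeps the inverse stable without visibly moving the
# boundary.

#' Fit a linear discriminant model
#'
#' @param x Numeric matrix `[n x p]` of (typically normalized) features.
#' @param y Class labels (character or factor), at least 2 classes with at
#'   least 2 frames each.
#' @param priors `"empirical"` (class frequencies) or `"uniform"`.
#' @param lambda Diagonal shrinkage weight in `[0, 1]` applied to the pooled
#'   covariance (default 1e-3; recorded in the model).
#' @param mask Optional integer column mask (e.g. from [sensor_mask()]);
#'   the model is fitted on `x[, mask]` and remembers the mask.
#' @return An `lda_model` with class means, pooled (shrunk) covariance,
#'   priors, the precomputed discriminant weights, `lambda` and `mask`.
#' @export
fit_lda <- function(x, y, priors = c("empirical", "uniform"),
                    lambda = 1e-3, mask = NULL) {
  priors <- match.arg(priors)
  x <- as.matrix(x)
  if (!is.null(mask)) x <- x[, mask, drop = FALSE]
  if (any(!is.finite(x))) stop("fit_lda: non-finite feature values",
                               call. = FALSE)
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]",
                                     call. = FALSE)
  y <- as.character(y)
  classes <- sort(unique(y))
  K <- length(classes)
  if (K < 2) stop("fit_lda: need at least 2 classes", call. = FALSE)
  # keep the canonical gesture order when y is drawn from it
  if (all(classes %in% movement_labels())) {
    classes <- movement_labels()[movement_labels() %in% classes]
  }
  n <- nrow(x); p <- ncol(x)
  counts <- vapply(classes, function(k) sum(y == k), numeric(1))
  short <- classes[counts < 2]
  if (length(short) > 0) {
    stop("fit_lda: class(es) with fewer than 2 frames: ",
         paste(short, collapse = ","), call. = FALSE)
  }
  means <- t(vapply(classes, function(k) {
    colMeans(x[y == k, , drop = FALSE])
  }, numeric(p)))
  S <- matrix(0, p, p)
  for (ki in seq_len(K)) {
    xc <- x[y == classes[ki], , drop = FALSE]
    xc <- xc - matrix(means[ki, ], nrow(xc), p, byrow = TRUE)
    S <- S + crossprod(xc)
  }
  S <- S / (n - K)
  S <- (1 - lambda) * S + lambda * diag(diag(S), p)
  Sinv <- tryCatch(chol2inv(chol(S)),
                   error = function(e) {
                     stop("pooled covariance is singular after shrinkage; ",
                          "increase lambda (current ", lambda, ")",
                          call. = FALSE)
                   })
  pri <- if (priors == "empirical") counts / n else rep(1 / K, K)
  W <- Sinv %*% t(means)                       # p x K
  b <- -0.5 * colSums(t(means) * W) + log(pri) # length K
  structure(list(classes = classes, means = means, cov = S, priors = pri,
                 lambda = lambda, mask = mask, W = W, b = b,
                 p = p),
            class = "lda_model")
}

#' Predict with a linear discriminant model
#'
#' Computes all class discriminant scores `delta_k(x)` and returns the
#' argmax label per row; ties are broken deterministically by the lowest
#' class index.
#'
#' @param model An `lda_model`.
#' @param x Numeric vector (one frame) or matrix `[n x p]`. If the model was
#'   fitted with a column mask and `x` has the full 68 columns, the mask is
#'   applied automatically.
#' @return `list(label = character(n), scores = [n x K] matrix)` with
#'   columns named by class.
#' @export
predict_lda <- function(model, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (!is.null(model$mask) && ncol(x) != model$p) {
    x <- x[, model$mask, drop = FALSE]
  }
  if (ncol(x) != model$p) {
    stop("predict_lda: got ", ncol(x), " features, model expects ", model$p,
         call. = FALSE)
  }
  scores <- x %*% model$W + matrix(model$b, nrow(x), length(model$b),
                                   byrow = TRUE)
  colnames(scores) <- model$classes
  lab <- model$classes[max.col(scores, ties.method = "first")]
  list(label = lab, scores = scores)
}

#' Serialize / restore an LDA model as JSON
#'
#' Model artifacts are plain JSON (means, covariance, priors, shrinkage,
#' mask, feature-order hash) — portable and diffable.
#'
#' @param model An `lda_model`.
#' @param path Output file.
#' @return `path` invisibly (`write_lda`); the restored model (`read_lda`).
#' @export
write_lda <- function(model, path) {
  obj <- list(classes = model$classes, means = model$means, cov = model$cov,
              priors = model$priors, lambda = model$lambda,
              mask = model$mask,
              feature_order_hash = feature_order_hash())
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lda
#' @export
read_lda <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$feature_order_hash, feature_order_hash())) {
    warning("model was fitted under a different feature ordering",
            call. = FALSE)
  }
  means <- as.matrix(obj$means)
  S <- as.matrix(obj$cov)
  Sinv <- chol2inv(chol(S))
  W <- Sinv %*% t(means)
  b <- -0.5 * colSums(t(means) * W) + log(obj$priors)
  structure(list(classes = obj$classes, means = means, cov = S,
                 priors = obj$priors, lambda = obj$lambda,
                 mask = obj$mask, W = W, b = b, p = ncol(means)),
            class = "lda_model")
}

feature_order_hash <- function() {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(feature_names(), f)
  unname(tools::md5sum(f))
}
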