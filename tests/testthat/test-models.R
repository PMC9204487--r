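# LDA from the discriminant function; comparison classifiers; importance

test_that("symmetric two-class LDA yields the midpoint hyperplane", {
  set.seed(31)
  base <- matrix(rnorm(400 * 4), ncol = 4)
  mu <- c(1, 0, 0, 0)
  x <- rbind(base + matrix(mu, 400, 4, byrow = TRUE),
             -(base + matrix(mu, 400, 4, byrow = TRUE)))
  y <- rep(c("A", "B"), each = 400)
  m <- fit_lda(x, y, lambda = 0)
  # discriminants tie exactly on the hyperplane x1 = 0
  sc <- predict_lda(m, rep(0, 4))$scores
  expect_equal(unname(sc[1, "A"]), unname(sc[1, "B"]))
  expect_equal(predict_lda(m, c(0.5, 0, 0, 0))$label, "A")
  expect_equal(predict_lda(m, c(-0.5, 0, 0, 0))$label, "B")
  # x exactly at a class mean classifies as that class
  expect_equal(predict_lda(m, m$means["A", ])$label, "A")
  expect_equal(predict_lda(m, m$means["B", ])$label, "B")
})

test_that("lambda = 1 gives an exactly diagonal pooled covariance", {
  set.seed(32)
  x <- matrix(rnorm(300 * 5), ncol = 5)
  y <- rep(c("A", "B", "C"), each = 100)
  m <- fit_lda(x, y, lambda = 1)
  off <- m$cov; diag(off) <- 0
  expect_true(all(off == 0))
})

test_that("class means are recovered on synthetic Gaussians", {
  set.seed(33)
  mus <- rbind(c(0, 0, 0), c(2, -1, 1), c(-1, 2, -2))
  x <- do.call(rbind, lapply(1:3, function(k) {
    matrix(rnorm(5000 * 3), ncol = 3) + matrix(mus[k, ], 5000, 3, byrow = TRUE)
  }))
  y <- rep(c("A", "B", "C"), each = 5000)
  m <- fit_lda(x, y)
  expect_lt(max(abs(m$means - mus)), 0.05)
  expect_equal(sum(m$priors), 1)
})

test_that("LDA error contracts fit_lda's stated preconditions", {
  x <- matrix(rnorm(40), ncol = 2)
  expect_error(fit_lda(x, rep("A", 20)), "2 classes")
  expect_error(fit_lda(x, c("B", rep("A", 19))), "fewer than 2 frames: B")
  x2 <- cbind(rnorm(20), 0)  # zero-variance column -> singular at lambda = 0
  expect_error(fit_lda(x2, rep(c("A", "B"), 10), lambda = 0), "singular")
  m <- fit_lda(x, rep(c("A", "B"), 10))
  expect_error(predict_lda(m, matrix(0, 1, 5)), "features")
})

test_that("prediction is invariant to invertible affine re-scaling", {
  set.seed(34)
  x <- matrix(rnorm(600 * 4), ncol = 4) +
    matrix(rep(c(0, 1.5), each = 300), 600, 4)
  y <- rep(c("A", "B"), each = 300)
  A <- matrix(rnorm(16), 4, 4) + diag(4) * 2
  shift <- rnorm(4)
  xt <- x %*% A + matrix(shift, 600, 4, byrow = TRUE)
  set.seed(35)
  xte <- matrix(rnorm(200 * 4), ncol = 4)
  xte_t <- xte %*% A + matrix(shift, 200, 4, byrow = TRUE)
  p1 <- predict_lda(fit_lda(x, y, lambda = 0), xte)$label
  p2 <- predict_lda(fit_lda(xt, y, lambda = 0), xte_t)$label
  expect_identical(p1, p2)
})

test_that("predictions agree with MASS::lda on random Gaussian data", {
  skip_if_not_installed("MASS")
  set.seed(36)
  x <- matrix(rnorm(900 * 6), ncol = 6) +
    matrix(rep(c(0, 1, -1), each = 300), 900, 6)
  y <- rep(c("A", "B", "C"), each = 300)
  xte <- matrix(rnorm(300 * 6), ncol = 6)
  ours <- predict_lda(fit_lda(x, y, lambda = 0), xte)$label
  theirs <- as.character(predict(MASS::lda(x, grouping = y), xte)$class)
  expect_identical(ours, theirs)
})

test_that("LDA models survive a JSON round-trip", {
  set.seed(37)
  x <- matrix(rnorm(200 * 3), ncol = 3) +
    matrix(rep(c(0, 2), each = 100), 200, 3)
  y <- rep(c("A", "B"), each = 100)
  m <- fit_lda(x, y)
  f <- withr::local_tempfile(fileext = ".json")
  write_lda(m, f)
  m2 <- read_lda(f)
  xte <- matrix(rnorm(50 * 3), ncol = 3)
  expect_identical(predict_lda(m, xte)$label, predict_lda(m2, xte)$label)
  expect_equal(m2$lambda, m$lambda)
})

test_that("comparators honor their frozen settings and contracts", {
  set.seed(38)
  # KNN: a query present three times in training returns its own label
  xtr <- rbind(matrix(rnorm(30), ncol = 3), matrix(0.5, 3, 3))
  ytr <- c(rep("A", 10), rep("B", 3))
  knn <- fit_comparator(comparator_spec("knn"), xtr, ytr)
  expect_equal(predict_comparator(knn, rep(0.5, 3)), "B")
  # RF with a fixed seed is reproducible
  x <- matrix(rnorm(300 * 5), ncol = 5) +
    matrix(rep(c(0, 1, 2), each = 100), 300, 5)
  y <- rep(c("A", "B", "C"), each = 100)
  rf1 <- fit_comparator(comparator_spec("rf"), x, y, seed = 9L)
  rf2 <- fit_comparator(comparator_spec("rf"), x, y, seed = 9L)
  xte <- matrix(rnorm(100 * 5), ncol = 5)
  expect_identical(predict_comparator(rf1, xte), predict_comparator(rf2, xte))
  expect_error(comparator_spec("mlp"), "unknown")
})

test_that("all four comparators master a well-separated 3-class problem", {
  set.seed(39)
  x <- matrix(rnorm(600 * 4, sd = 0.3), ncol = 4) +
    matrix(rep(c(0, 2, 4), each = 200), 600, 4)
  y <- rep(c("A", "B", "C"), each = 200)
  idx <- sample(600, 450)
  for (kind in c("dt", "knn", "rf", "svm")) {
    fit <- fit_comparator(comparator_spec(kind), x[idx, ], y[idx], seed = 2L)
    acc <- mean(predict_comparator(fit, x[-idx, ]) == y[-idx])
    expect_gte(acc, 0.95)
  }
})

test_that("Gini importance is normalized, top-10, and finds the planted feature", {
  set.seed(40)
  n <- 400
  x <- matrix(rnorm(n * 68, sd = 1), n, 68)
  y <- rep(c("CG", "SG"), each = n / 2)
  planted <- which(feature_names() == "fmg3_mav")
  x[y == "SG", planted] <- x[y == "SG", planted] + 4
  imp <- gini_importance(x, y, seed = 3L)
  expect_equal(nrow(imp), 10L)
  expect_equal(imp$feature[1], "fmg3_mav")
  expect_equal(imp$modality[1], "FMG")
  expect_equal(sum(attr(imp, "all_importances")), 1, tolerance = 1e-9)
  expect_true(all(attr(imp, "all_importances") >= 0))
})
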