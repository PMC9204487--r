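# Cross-validation, ablation, voting, grouping, real-time simulation

test_that("leave-one-trial-out produces one fold per trial and conserves accuracy", {
  sf <- fast_subject()
  res <- loto_cv(sf$offline)
  expect_equal(res$n_folds, 5L)
  expect_length(res$fold_accuracy, 5L)
  cm <- res$confusion
  expect_equal(sum(cm), length(sf$offline$label[sf$offline$valid]))
  expect_true(all(rowSums(unclass(cm)) > 0))
  # aggregated-confusion accuracy equals the frame-weighted fold mean
  # (balanced folds here, so the plain mean coincides)
  expect_equal(accuracy(cm), mean(res$fold_accuracy), tolerance = 1e-10)
  expect_error(loto_cv(sf$realtime[[1]]), ">= 2 trials")
})

test_that("confusion matrix bookkeeping is exact", {
  cm <- confusion_matrix(c("MF", "MF", "ME", "NM"),
                         c("MF", "ME", "ME", "NM"))
  expect_equal(accuracy(cm), 0.75)
  expect_equal(unname(attr(cm, "recall")[c("MF", "ME", "NM")]),
               c(0.5, 1, 1))
  expect_equal(sum(cm), 4)
  expect_equal(unclass(cm)["MF", "ME"], 1)
})

test_that("ablation returns the 7 configurations over shared features", {
  sf <- fast_subject()
  abl <- ablate_sensors(sf$offline)
  expect_equal(nrow(abl), 7L)
  expect_equal(sort(abl$n_features), c(8L, 12L, 20L, 48L, 56L, 60L, 68L))
  expect_true(all(abl$accuracy >= 0 & abl$accuracy <= 1))
  # reproducible bit-for-bit on the deterministic LDA path
  abl2 <- ablate_sensors(sf$offline)
  expect_identical(abl, abl2)
})

test_that("majority vote follows count, then summed-score tie-break", {
  expect_equal(majority_vote(rep(c("A", "B"), c(7, 3))), "A")
  sc <- matrix(0, 10, 2, dimnames = list(NULL, c("A", "B")))
  labs <- rep(c("A", "B"), each = 5)
  sc[labs == "A", "A"] <- 1
  sc[labs == "B", "B"] <- 1.2
  expect_equal(majority_vote(labs, sc), "B")
  sc[labs == "A", "A"] <- 2
  expect_equal(majority_vote(labs, sc), "A")
  # no scores: deterministic lowest class index
  expect_equal(majority_vote(c("ME", "MF")), "MF")
  expect_error(majority_vote(character(0)), "no predictions")
  expect_error(majority_vote(c("A", "B"), valid = c(FALSE, FALSE)),
               "no valid")
})

test_that("default grouping is valid; violations are named", {
  g <- grouping_scheme()
  rep <- validate_grouping(g)
  expect_true(rep$valid)
  bad <- list(c("CG", "SG", "MF"), c("ME", "TA", "FP"),
              c("HG", "O", "FS"), c("WF", "WE", "NM"))
  rep2 <- validate_grouping(bad)
  expect_false(rep2$valid)
  expect_match(paste(rep2$violations, collapse = " "), "CG,SG")
  expect_error(grouping_scheme(bad), "CG,SG")
  rep3 <- validate_grouping(list(c("MF", "ME")))
  expect_false(rep3$valid)
  expect_match(paste(rep3$violations, collapse = " "), "missing")
})

test_that("greedy grouping beats random grouping on a synthetic confusion matrix", {
  set.seed(51)
  labs <- c("MF", "ME", "TA", "O", "CG", "SG")
  m <- matrix(rpois(36, 2), 6, 6, dimnames = list(labs, labs))
  diag(m) <- 60
  m["CG", "SG"] <- 25; m["SG", "CG"] <- 22; m["TA", "O"] <- 18
  cm <- structure(m, class = "confusion_matrix")
  greedy <- greedy_grouping(cm, group_sizes = c(3L, 3L))
  greedy_cost <- within_group_confusion(greedy, cm)
  # brute force over all 10 partitions of 6 labels into two triples
  combos <- utils::combn(labs[-1], 2, simplify = FALSE)
  costs <- vapply(combos, function(pair) {
    g1 <- c(labs[1], pair)
    within_group_confusion(list(g1, setdiff(labs, g1)), cm)
  }, numeric(1))
  expect_equal(greedy_cost, min(costs))   # greedy is optimal here
  expect_lt(greedy_cost, mean(costs))     # and strictly beats average/random
})

test_that("grouped real-time simulation votes once per movement per fold", {
  sf <- fast_subject()
  rt <- simulate_realtime(sf, protocol = fast_protocol())
  expect_equal(nrow(rt$decisions), 12L * 5L)
  expect_equal(unname(table(rt$decisions$fold)), rep(12L, 5L),
               ignore_attr = TRUE)
  expect_length(rt$group_accuracy, 4L)
  expect_true(all(rt$group_accuracy >= 0 & rt$group_accuracy <= 1))
  # voted labels stay inside the movement's own group
  g <- grouping_scheme()$groups
  for (i in seq_len(nrow(rt$decisions))) {
    gi <- rt$decisions$group[i]
    expect_true(rt$decisions$voted[i] %in% g[[gi]])
  }
})

test_that("strongly attenuated subjects still beat group chance level", {
  sf <- fast_subject(profile = impairment_profile(gamma = 0.2))
  rt <- simulate_realtime(sf, protocol = fast_protocol())
  expect_gt(rt$accuracy, 1 / 3)
})

test_that("pearson correlation matches the textbook formula", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_corr(a, 2 * a + 1)$r, 1)
  b <- c(1, -2, 2, -2, 1)  # zero-mean, orthogonal to centered a
  expect_equal(pearson_corr(a, b)$r, 0, tolerance = 1e-12)
  set.seed(52)
  x <- rnorm(20); y <- rnorm(20)
  # direct-formula oracle
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  pc <- pearson_corr(x, y)
  expect_equal(pc$r, r_direct, tolerance = 1e-12)
  tstat <- r_direct * sqrt(18 / (1 - r_direct^2))
  expect_equal(pc$p, 2 * pt(-abs(tstat), 18), tolerance = 1e-12)
  expect_error(pearson_corr(a, rep(1, 5)), "constant")
  expect_error(pearson_corr(1:2, 1:2), ">= 3")
})

test_that("demo report carries all four sections with provenance", {
  rep <- run_demo(seed = 3L, n_subjects = 1L, cfg = fast_cfg(),
                  protocol = fast_protocol(), progress = FALSE)
  expect_named(rep, c("provenance", "loto", "ablation", "importance",
                      "realtime"))
  expect_equal(nrow(rep$ablation), 7L)
  expect_equal(nrow(rep$importance), 10L)
  expect_equal(rep$provenance$window_samples$emg_win, 428L)
  expect_true(nzchar(rep$provenance$config_hash))
  rep2 <- run_demo(seed = 3L, n_subjects = 1L, cfg = fast_cfg(),
                   protocol = fast_protocol(), progress = FALSE)
  expect_equal(rep$loto$mean_accuracy, rep2$loto$mean_accuracy)
  expect_identical(rep$ablation, rep2$ablation)
})
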