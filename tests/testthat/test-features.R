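# Time-domain features, AR coefficients, normalization

test_that("feature examples evaluate to their hand-checked values", {
  expect_equal(unname(mav(c(1, -1, 2, -2))), 1.5)
  expect_equal(unname(mav(rep(0, 10))), 0)
  expect_equal(unname(wl(c(0, 1, 0, 1))), 3)
  expect_equal(unname(wl(rep(2, 5))), 0)
  expect_equal(unname(zc(c(1, -1, 1, -1), eps = 0.5)), 3)
  expect_equal(unname(zc(c(1, -1, 1, -1), eps = 3)), 0)   # |delta| = 2 < 3
  expect_equal(unname(ssc(c(0, 1, 0, 1, 0), eps = 0.5)), 3)
  expect_equal(unname(ssc(1:10, eps = 0)), 0)              # monotone ramp
  expect_error(mav(numeric(0)), "empty")
  expect_error(wl(1), "2 samples")
  expect_error(ssc(c(1, 2), eps = 0), "3 samples")
})

test_that("vectorized features match brute-force oracles on random windows", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(4:200, 1)
    x <- rnorm(n, sd = 10^runif(1, -5, 1))
    eps <- sample(c(0, 4e-6, sd(x) / 2), 1)
    expect_equal(unname(mav(x)), oracle_mav(x), tolerance = 1e-12)
    expect_equal(unname(wl(x)), oracle_wl(x), tolerance = 1e-12)
    expect_identical(as.integer(zc(x, eps)), as.integer(oracle_zc(x, eps)))
    expect_identical(as.integer(ssc(x, eps)), as.integer(oracle_ssc(x, eps)))
  }
})

test_that("ZC and SSC are invariant under joint signal/threshold scaling", {
  set.seed(22)
  for (i in 1:50) {
    x <- rnorm(100)
    eps <- runif(1, 0, 1)
    s <- 10^runif(1, -3, 3)
    expect_identical(zc(x, eps), zc(s * x, s * eps))
    expect_identical(ssc(x, eps), ssc(s * x, s * eps))
  }
})

test_that("Burg AR matches stats::ar.burg and recovers known processes", {
  set.seed(23)
  for (i in 1:25) {
    x <- as.numeric(arima.sim(list(ar = c(0.4, -0.2, 0.1, -0.05)), 428))
    expect_equal(unname(ar_coeffs(x, 4)[, 1]),
                 unname(stats::ar.burg(x, aic = FALSE, order.max = 4)$ar),
                 tolerance = 1e-10)
  }
  # least-squares fallback agrees with Burg on long stationary windows
  x <- as.numeric(arima.sim(list(ar = c(0.5, -0.25, 0.1, -0.05)), 2e4))
  expect_equal(unname(ar_coeffs(x, 4, method = "ls")[, 1]),
               unname(ar_coeffs(x, 4, method = "burg")[, 1]),
               tolerance = 0.01)
  # constant window yields zero coefficients instead of failing
  expect_equal(unname(ar_coeffs(rep(0, 428), 4)[, 1]), rep(0, 4))
  expect_error(ar_coeffs(rnorm(8), 4), "too short")
})

test_that("extracted frames carry 68 features in the frozen layout", {
  cfg <- fast_cfg()
  rec <- generate_trial(cfg, trial_id = 1L)
  segs <- lapply(segment_by_triggers(rec, cfg$movement_duration_s),
                 trim_segment, rule = fast_trim())
  fm <- extract_features(rec, segs)
  expect_equal(ncol(fm$x), 68L)
  expect_identical(colnames(fm$x), feature_names())
  # spot-check one frame against the per-window functions
  fr <- make_frames(segs[[3]])
  w <- rec$emg[(fr$emg_start[5] + 1):fr$emg_end[5], 2]
  row <- which(fm$label == segs[[3]]$label)[5]
  expect_equal(unname(fm$x[row, "emg2_mav"]), unname(mav(w)))
  expect_equal(unname(fm$x[row, "emg2_wl"]), unname(wl(w)))
  expect_equal(unname(fm$x[row, "emg2_zc"]), unname(zc(w, 4e-6)))
  expect_equal(unname(fm$x[row, "emg2_ar3"]), unname(ar_coeffs(w, 4)[3, 1]))
  lw <- rec$fmg[(fr$low_start[5] + 1):fr$low_end[5], 7]
  expect_equal(unname(fm$x[row, "fmg7_mav"]), unname(mav(lw)))
  # rest frames sit far below active-class amplitude
  expect_lt(mean(fm$x[fm$label == "NM", "emg1_mav"]),
            mean(fm$x[fm$label == "MF", "emg1_mav"]) / 5)
})

test_that("feature extraction is deterministic", {
  cfg <- fast_cfg()
  rec <- generate_trial(cfg, trial_id = 1L)
  segs <- lapply(segment_by_triggers(rec, cfg$movement_duration_s),
                 trim_segment, rule = fast_trim())
  expect_identical(extract_features(rec, segs), extract_features(rec, segs))
})

test_that("per-trial normalization zeroes means, units sds, and inverts", {
  sf1 <- fast_subject(n_trials = 2L)
  fm <- sf1$offline
  fmz <- zscore_by_trial(fm)
  for (tr in unique(fmz$trial_id)) {
    z <- fmz$x[fmz$trial_id == tr, ]
    expect_lt(max(abs(colMeans(z))), 1e-9)
    expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-9)
  }
  back <- denormalize(fmz)
  expect_equal(back$x, fm$x, tolerance = 1e-9)
  # constant column collapses to zero with a message
  fm2 <- fm
  fm2$x[, 5] <- 7
  expect_message(fmz2 <- zscore_by_trial(fm2), "constant")
  expect_true(all(fmz2$x[, 5] == 0))
  # single-frame trial refuses
  fm3 <- fm
  fm3$trial_id[1] <- 99L
  expect_error(zscore_by_trial(fm3), "fewer than 2")
})
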