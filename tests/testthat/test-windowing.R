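# Segmentation, trimming, multirate frame enumeration

test_that("derived window sample counts are the frozen integers", {
  w <- windowing_config()
  expect_identical(w$emg_win, 428L)
  expect_identical(w$emg_step, 107L)
  expect_identical(w$low_win, 2L)
})

test_that("trigger segmentation follows rate arithmetic on both clocks", {
  rec <- tiny_recording()
  rec$triggers <- data.frame(onset_s = 10.0, label = "MF")
  # fake a long enough recording by direct range math on a synthetic trial
  cfg <- synth_config()
  full <- generate_trial(cfg, trial_id = 1L)
  full$triggers <- data.frame(onset_s = 10.0, label = "MF")
  segs <- segment_by_triggers(full, 6)
  expect_length(segs, 1L)
  s <- segs[[1]]
  expect_equal(c(s$emg_start, s$emg_end), c(19260L, 30816L))
  expect_equal(c(s$low_start, s$low_end), c(360L, 576L))
  ts <- trim_segment(s)
  expect_equal(c(ts$emg_start, ts$emg_end), c(23112L, 29853L))
  expect_equal(ts$emg_end - ts$emg_start, 6741L)  # 3.5 s retained
  # head = tail = 0 is the identity
  expect_equal(trim_segment(s, trim_rule(0, 0)), s)
  # too-short segment refuses to trim
  expect_error(trim_segment(ts, trim_rule(3, 1)), "too short")
})

test_that("zero triggers give an empty segment list; late triggers drop", {
  rec <- tiny_recording(triggers = data.frame(onset_s = numeric(0),
                                              label = character(0)))
  expect_length(segment_by_triggers(rec, 6), 0L)
  rec2 <- tiny_recording(triggers = data.frame(onset_s = 0.49,
                                               label = "MF"))
  expect_warning(segs <- segment_by_triggers(rec2, 6), "beyond")
  expect_length(segs, 0L)
})

test_that("a default synthetic trial yields 12 segments in generator order", {
  cfg <- fast_cfg()
  rec <- generate_trial(cfg, trial_id = 1L)
  segs <- segment_by_triggers(rec, cfg$movement_duration_s)
  expect_length(segs, 12L)
  expect_equal(vapply(segs, `[[`, character(1), "label"), movement_labels())
})

test_that("frame count matches the closed form and brute-force enumeration", {
  w <- windowing_config()
  seg <- mmgesture:::new_segment("MF", 0, 6741, 0, 126, 1L)
  expect_equal(nrow(make_frames(seg, w)), 60L)
  seg1 <- mmgesture:::new_segment("MF", 0, 428, 0, 8, 1L)
  expect_equal(nrow(make_frames(seg1, w)), 1L)
  short <- mmgesture:::new_segment("MF", 0, 427, 0, 8, 1L)
  expect_warning(fr <- make_frames(short, w), "shorter")
  expect_equal(nrow(fr), 0L)
  set.seed(11)
  for (L in sample(428:20000, 25)) {
    seg <- mmgesture:::new_segment("MF", 0, L, 0, ceiling(L / 1926 * 36), 1L)
    expect_equal(nrow(make_frames(seg, w)), oracle_frame_count(L, 428, 107),
                 label = paste("L =", L))
  }
})

test_that("each frame pairs with the latest low-rate window ending by the frame end", {
  w <- windowing_config()
  seg <- mmgesture:::new_segment("MF", 0, 6741, 0, 126, 1L)
  fr <- make_frames(seg, w)
  for (i in seq_len(nrow(fr))) {
    end_time <- fr$low_end[i] / 36
    expect_lte(end_time, fr$t_end[i] + 1e-9)
    # the next disjoint window would end after the EMG frame (unless clamped
    # at the segment boundary)
    if (fr$low_end[i] + 2 <= seg$low_end) {
      expect_gt((fr$low_end[i] + 2) / 36, fr$t_end[i])
    }
    expect_equal((fr$low_start[i] - seg$low_start) %% 2, 0)
  }
})

test_that("out-of-range FMG samples are marked and invalidate their frames", {
  rec <- tiny_recording()
  out <- drop_invalid_fmg(rec)
  expect_identical(out$dropped, integer(0))
  expect_identical(out$rec, rec)
  rec$fmg[11, 3] <- 200  # 0-based index 10
  expect_identical(drop_invalid_fmg(rec)$dropped, 10L)
  # frames overlapping the dropped index are invalid downstream
  seg <- mmgesture:::new_segment("MF", 0, nrow(rec$emg), 0, nrow(rec$fmg), 3L)
  fm <- extract_features(rec, list(seg), dropped = 10L)
  fr <- make_frames(seg)
  hit <- fr$low_start <= 10 & 10 < fr$low_end
  expect_identical(fm$valid, !hit)
})

test_that("injected clipping fraction lands within its binomial interval", {
  hits <- sapply(1:10, function(seed) {
    cfg <- fast_cfg(seed = seed, clip_fraction = 0.01)
    rec <- generate_trial(cfg, trial_id = 1L)
    length(drop_invalid_fmg(rec)$dropped) / nrow(rec$fmg)
  })
  n <- round((12 * 1.5 + 11 * 0.5) * 36)
  ci <- stats::qbinom(c(0.0005, 0.9995), n * 10, 0.01) / (n * 10)
  expect_gte(mean(hits), ci[1])
  expect_lte(mean(hits), ci[2])
})
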