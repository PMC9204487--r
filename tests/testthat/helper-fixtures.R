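# Shared fixtures: compact synthetic configurations and independent
# brute-force feature oracles.

# short blocks keep unit tests fast; structure (12 movements, triggers,
# multirate clocks) is unchanged
fast_cfg <- function(seed = 1L, ...) {
  synth_config(movement_duration_s = 1.5, inter_movement_gap_s = 0.5,
               seed = seed, ...)
}

fast_trim <- function() trim_rule(0.5, 0.25)

fast_protocol <- function() {
  realtime_protocol(train_head_s = 0.5, train_tail_s = 0.25,
                    test_offset_s = 0.3, vote_window = 10L)
}

fast_subject <- function(cfg = fast_cfg(), profile = impairment_profile(),
                         n_trials = cfg$n_trials, subject_index = 1L) {
  recs <- lapply(seq_len(n_trials), function(k) {
    generate_trial(cfg, profile, trial_id = k,
                   subject_id = sprintf("S%02d", subject_index),
                   subject_index = subject_index)
  })
  subject_features(recs, cfg$movement_duration_s,
                   protocol = fast_protocol())
}

# tiny hand-built recording for IO tests (0.5 s)
tiny_recording <- function(seed = 42L, triggers = NULL) {
  set.seed(seed)
  n_emg <- round(0.5 * 1926); n_low <- round(0.5 * 36)
  if (is.null(triggers)) {
    triggers <- data.frame(onset_s = c(0.05, 0.25), label = c("MF", "NM"))
  }
  multimodal_recording(
    emg = matrix(rnorm(n_emg * 6, sd = 1e-4), n_emg, 6),
    fmg = matrix(50 + rnorm(n_low * 8), n_low, 8),
    imu = matrix(rnorm(n_low * 12), n_low, 12),
    triggers = triggers,
    subject_id = "S99", trial_id = 3L
  )
}

# draw under a fixed seed without touching the session RNG state
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# ---- independent brute-force feature oracles (plain loops) ----

oracle_mav <- function(x) {
  s <- 0
  for (v in x) s <- s + abs(v)
  s / length(x)
}

oracle_wl <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1)) s <- s + abs(x[i + 1] - x[i])
  s
}

oracle_zc <- function(x, eps) {
  n <- 0
  for (i in seq_len(length(x) - 1)) {
    if (x[i] * x[i + 1] < 0 && abs(x[i] - x[i + 1]) >= eps) n <- n + 1
  }
  n
}

oracle_ssc <- function(x, eps) {
  n <- 0
  for (i in 2:(length(x) - 1)) {
    d1 <- x[i] - x[i - 1]; d2 <- x[i] - x[i + 1]
    if (d1 * d2 > 0 && max(abs(d1), abs(d2)) >= eps) n <- n + 1
  }
  n
}

# brute-force window placement count
oracle_frame_count <- function(L, win, step) {
  n <- 0; s <- 0
  while (s + win <= L) { n <- n + 1; s <- s + step }
  n
}
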