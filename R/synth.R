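# Synthetic multimodal recordings
# -------------------------------
# Emulates the training-phase protocol: each trial presents the 12 gestures
# in the fixed label order, 6 s per movement with 4 s rest gaps, EMG at
# 1926 Hz and FMG/IMU at 36 Hz, with a trigger at each movement onset.
#
# Signal model (per movement block c with raised-cosine envelope env_c):
#   EMG ch j : gain * (floor + gamma * A[c,j] * env_c(t)) * n_j(t),
#              n_j = unit-variance Gaussian noise band-limited to 20-450 Hz
#              (amplitude-modulated band-limited noise, the standard sEMG
#              surrogate)
#   FMG ch k : baseline + gamma * F[c,k] * env_c(t) + slow sinusoidal drift
#              + white noise
#   IMU ch m : base[m] + gamma * M[c,m] * env_c(t) + white noise
#
# Class signature matrices A (EMG activation in [0,1]), F (FMG offsets) and
# M (IMU offsets) are fixed defaults engineered for designed
# complementarity: CG and SG share EMG+IMU rows and differ only in FMG;
# MF and HG share FMG+IMU rows and differ only in EMG; the rest class NM is
# all-zero. Finger movements carry near-zero IMU offsets (the IMU sits on
# the wrist), wrist/forearm movements carry large ones.

default_emg_signatures <- function() {
  m <- rbind(
    MF = c(0.90, 0.70, 0.20, 0.10, 0.60, 0.30),
    ME = c(0.20, 0.30, 0.80, 0.90, 0.10, 0.50),
    HG = c(0.50, 0.90, 0.10, 0.30, 0.80, 0.20),
    TA = c(0.30, 0.20, 0.40, 0.10, 0.20, 0.60),
    O  = c(0.40, 0.30, 0.30, 0.20, 0.30, 0.50),
    CG = c(0.70, 0.50, 0.40, 0.60, 0.50, 0.40),
    SG = c(0.70, 0.50, 0.40, 0.60, 0.50, 0.40),  # == CG: FMG must resolve
    WF = c(0.80, 0.20, 0.10, 0.70, 0.90, 0.20),
    WE = c(0.10, 0.80, 0.90, 0.20, 0.10, 0.70),
    FP = c(0.30, 0.60, 0.50, 0.80, 0.20, 0.10),
    FS = c(0.60, 0.10, 0.70, 0.30, 0.40, 0.90),
    NM = rep(0, 6)
  )
  colnames(m) <- paste0("ch", 1:6)
  m
}

default_fmg_signatures <- function() {
  m <- rbind(
    MF = c(8, 6, 2, 1, 5, 3, 2, 4),
    ME = c(1, 2, 7, 8, 2, 5, 6, 1),
    HG = c(8, 6, 2, 1, 5, 3, 2, 4),  # == MF: EMG must resolve
    TA = c(2, 1, 3, 2, 1, 4, 2, 3),
    O  = c(2, 2, 3, 2, 2, 4, 2, 3),  # near TA: confusable pair
    CG = c(6, 7, 5, 4, 6, 5, 7, 6),
    SG = c(3, 4, 8, 7, 2, 8, 4, 3),
    WF = c(7, 3, 1, 6, 8, 2, 3, 5),
    WE = c(2, 7, 6, 1, 3, 7, 5, 2),
    FP = c(4, 5, 4, 3, 7, 1, 6, 7),
    FS = c(5, 2, 6, 5, 4, 6, 1, 8),
    NM = rep(0, 8)
  )
  colnames(m) <- paste0("ch", 1:8)
  m
}

default_imu_signatures <- function() {
  m <- rbind(
    MF = c(0.20, 0.10, 0.10, 1.0, 0.5, 0.2, 0.10, 0.20, 0.10, 0.5, 0.3, 0.2),
    ME = c(0.10, 0.20, 0.10, 0.5, 1.0, 0.3, 0.20, 0.10, 0.10, 0.3, 0.5, 0.2),
    HG = c(0.20, 0.10, 0.10, 1.0, 0.5, 0.2, 0.10, 0.20, 0.10, 0.5, 0.3, 0.2),
    TA = c(0.10, 0.10, 0.20, 0.3, 0.2, 0.8, 0.10, 0.10, 0.20, 0.2, 0.2, 0.4),
    O  = c(0.10, 0.10, 0.15, 0.25, 0.2, 0.7, 0.10, 0.10, 0.15, 0.2, 0.2, 0.35),
    CG = c(0.15, 0.20, 0.10, 0.6, 0.4, 0.5, 0.15, 0.10, 0.10, 0.4, 0.3, 0.3),
    SG = c(0.15, 0.20, 0.10, 0.6, 0.4, 0.5, 0.15, 0.10, 0.10, 0.4, 0.3, 0.3),
    WF = c(1.50, 0.50, 1.00, 30, 10, 5, 2.0, 1.0, 3.0, 15, 5, 2),
    WE = c(-1.20, 0.40, 1.10, -25, 8, 4, -2.0, 1.5, 2.5, -14, 4, 2),
    FP = c(0.80, 1.50, 0.60, 5, 30, 12, 3.0, -2.0, 1.0, 4, 2, 18),
    FS = c(0.70, -1.40, 0.50, 4, -28, -10, -3.0, 2.0, 1.5, 3, -2, -16),
    NM = rep(0, 12)
  )
  colnames(m) <- imu_channel_names()
  m
}

#' Synthetic-cohort configuration
#'
#' Defaults reproduce the training-phase structure: 12 movements per trial in
#' the fixed label order, 6 s per movement, 4 s inter-movement rest, five
#' trials per subject (trial duration 12*6 + 11*4 = 116 s). Class signatures
#' default to fixed matrices engineered so that modalities are complementary
#' (see the package vignette); `NM` has all-zero signatures by construction.
#'
#' @param n_trials Trials per subject.
#' @param movement_duration_s,inter_movement_gap_s Block structure, seconds.
#' @param emg_gain EMG amplitude scale, volts (default 8e-4 V = 0.8 mV, a
#'   typical surface-EMG contraction amplitude).
#' @param emg_noise_floor Resting EMG modulation relative to `emg_gain`.
#' @param emg_band Band limits of the EMG carrier noise, Hz.
#' @param sigma_fmg,sigma_imu White-noise SDs for the low-rate streams
#'   (FMG signature offsets have scale ~1-8 units; IMU finger-movement
#'   offsets are deliberately near this noise floor).
#' @param fmg_baseline Resting FMG level, arbitrary units.
#' @param fmg_drift_amp,fmg_drift_period_s Slow sinusoidal FMG drift
#'   (defaults: 5% of baseline, 40 s period) motivating per-trial
#'   normalization.
#' @param ramp_s Raised-cosine envelope ramp at block edges, seconds.
#' @param clip_fraction Fraction of low-rate samples whose FMG reading is
#'   pushed beyond `fmg_valid_range` (exercises the out-of-range deletion
#'   rule); 0 disables injection.
#' @param fmg_valid_range Sensor measuring range recorded in session meta.
#' @param emg_signatures,fmg_signatures,imu_signatures 12-row signature
#'   matrices (rows in [movement_labels()] order).
#' @param seed Master seed; with subject/trial indices it fully determines
#'   every generated sample.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_trials = 5L,
                         movement_duration_s = 6,
                         inter_movement_gap_s = 4,
                         emg_gain = 8e-4,
                         emg_noise_floor = 0.02,
                         emg_band = c(20, 450),
                         sigma_fmg = 1,
                         sigma_imu = 0.3,
                         fmg_baseline = 50,
                         fmg_drift_amp = 2.5,
                         fmg_drift_period_s = 40,
                         ramp_s = 0.25,
                         clip_fraction = 0,
                         fmg_valid_range = c(0, 115),
                         emg_signatures = default_emg_signatures(),
                         fmg_signatures = default_fmg_signatures(),
                         imu_signatures = default_imu_signatures(),
                         seed = 1L) {
  cfg <- list(
    labels = movement_labels(),
    n_trials = as.integer(n_trials),
    movement_duration_s = movement_duration_s,
    inter_movement_gap_s = inter_movement_gap_s,
    emg_gain = emg_gain, emg_noise_floor = emg_noise_floor,
    emg_band = emg_band,
    sigma_fmg = sigma_fmg, sigma_imu = sigma_imu,
    fmg_baseline = fmg_baseline,
    fmg_drift_amp = fmg_drift_amp, fmg_drift_period_s = fmg_drift_period_s,
    ramp_s = ramp_s, clip_fraction = clip_fraction,
    fmg_valid_range = fmg_valid_range,
    emg_signatures = emg_signatures,
    fmg_signatures = fmg_signatures,
    imu_signatures = imu_signatures,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$movement_duration_s <= 0 || cfg$inter_movement_gap_s < 0 ||
      cfg$n_trials < 1) {
    stop("synth_config: durations must be positive and n_trials >= 1",
         call. = FALSE)
  }
  n <- length(cfg$labels)
  for (nm in c("emg_signatures", "fmg_signatures", "imu_signatures")) {
    if (nrow(cfg[[nm]]) != n) {
      stop("synth_config: ", nm, " must have one row per label", call. = FALSE)
    }
  }
  rest <- match(rest_label(), cfg$labels)
  if (!is.na(rest)) {
    if (any(cfg$emg_signatures[rest, ] != 0) ||
        any(cfg$fmg_signatures[rest, ] != 0) ||
        any(cfg$imu_signatures[rest, ] != 0)) {
      stop("synth_config: the rest class NM must have all-zero signatures",
           call. = FALSE)
    }
  }
  if (any(cfg$emg_signatures < 0) || any(cfg$emg_signatures > 1)) {
    stop("synth_config: EMG activations must lie in [0,1]", call. = FALSE)
  }
  invisible(cfg)
}

#' Impairment profile for a synthetic subject
#'
#' A coarse model of between-subject heterogeneity in motor impairment: a
#' scalar attenuation `gamma` in (0, 1] shrinking every class signature
#' toward rest, plus optional label-confusion jitter — with probability
#' `confusion_prob` a realized movement's signature is a convex blend with
#' its designated confusable partner (CG<->SG, TA<->O), emulating imprecise
#' execution of similar gestures.
#'
#' @param gamma Attenuation in (0, 1]; 1 = unimpaired signal strength.
#' @param confusion_prob Per-movement probability of signature blending.
#' @param blend_weight Blend weight in [0, 0.5] toward the partner class.
#' @return An `impairment_profile` list.
#' @export
impairment_profile <- function(gamma = 1, confusion_prob = 0,
                               blend_weight = 0.25) {
  if (!(gamma > 0 && gamma <= 1)) stop("gamma must lie in (0, 1]",
                                       call. = FALSE)
  if (blend_weight < 0 || blend_weight > 0.5) {
    stop("blend_weight must lie in [0, 0.5]", call. = FALSE)
  }
  if (confusion_prob < 0 || confusion_prob > 1) {
    stop("confusion_prob must lie in [0, 1]", call. = FALSE)
  }
  structure(list(gamma = gamma, confusion_prob = confusion_prob,
                 blend_weight = blend_weight),
            class = "impairment_profile")
}

confusable_partner <- function(label) {
  switch(label, CG = "SG", SG = "CG", TA = "O", O = "TA", NULL)
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic per-(subject, trial) seed below 2^31
derive_seed <- function(master, subject, trial) {
  as.integer((as.numeric(master) * 48271 + subject * 1009 + trial * 7) %%
               2147483629)
}

# unit-variance Gaussian noise band-limited by an FFT brick wall
bandlimited_noise <- function(n, band, rate) {
  x <- stats::rnorm(n)
  f <- abs(seq(0, rate, length.out = n + 1L)[seq_len(n)])
  f <- pmin(f, rate - f)  # two-sided frequency axis
  keep <- f >= band[1] & f <= band[2]
  X <- stats::fft(x)
  X[!keep] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / stats::sd(x)
}

# raised-cosine on/off envelope for block [t0, t1] evaluated at times t
block_envelope <- function(t, t0, t1, ramp) {
  env <- numeric(length(t))
  inb <- t >= t0 & t < t1
  u <- t[inb]
  e <- rep(1, length(u))
  if (ramp > 0) {
    rise <- u < t0 + ramp
    fall <- u > t1 - ramp
    e[rise] <- 0.5 - 0.5 * cos(pi * (u[rise] - t0) / ramp)
    e[fall] <- 0.5 - 0.5 * cos(pi * (t1 - u[fall]) / ramp)
  }
  env[inb] <- e
  env
}

#' Generate one synthetic trial
#'
#' Produces one [multimodal_recording()] containing all 12 movement blocks
#' in the fixed label order with a trigger at each onset, under the signal
#' model described in the package vignette. Output is fully determined by
#' `(cfg$seed, subject index, trial_id)`; the caller's RNG state is left
#' untouched.
#'
#' @param cfg A [synth_config()].
#' @param impairment An [impairment_profile()] or `NULL` (unimpaired).
#' @param trial_id Trial index (1-based).
#' @param subject_id Subject identifier string.
#' @param subject_index Integer used in seed derivation (default parses the
#'   digits of `subject_id`).
#' @return A `multimodal_recording`.
#' @export
generate_trial <- function(cfg, impairment = NULL, trial_id = 1L,
                           subject_id = "S01", subject_index = NULL) {
  validate_synth_config(cfg)
  if (is.null(impairment)) impairment <- impairment_profile()
  if (is.null(subject_index)) {
    subject_index <- suppressWarnings(as.integer(gsub("\\D", "", subject_id)))
    if (is.na(subject_index)) subject_index <- 0L
  }
  seed <- derive_seed(cfg$seed, subject_index, trial_id)
  with_seed(seed, {
    n_classes <- length(cfg$labels)
    dur <- n_classes * cfg$movement_duration_s +
      (n_classes - 1) * cfg$inter_movement_gap_s
    n_emg <- round(dur * EMG_RATE)
    n_low <- round(dur * LOW_RATE)
    t_emg <- (seq_len(n_emg) - 1) / EMG_RATE
    t_low <- (seq_len(n_low) - 1) / LOW_RATE
    onsets <- (seq_len(n_classes) - 1) *
      (cfg$movement_duration_s + cfg$inter_movement_gap_s)

    g <- impairment$gamma
    # realized per-block signatures (possibly blended with a confusable class)
    sa <- cfg$emg_signatures; sf <- cfg$fmg_signatures
    sm <- cfg$imu_signatures
    sig <- lapply(seq_len(n_classes), function(c) {
      a <- sa[c, ]; f <- sf[c, ]; m <- sm[c, ]
      partner <- confusable_partner(cfg$labels[c])
      if (!is.null(partner) && impairment$confusion_prob > 0 &&
          stats::runif(1) < impairment$confusion_prob) {
        p <- match(partner, cfg$labels)
        w <- impairment$blend_weight
        a <- (1 - w) * a + w * sa[p, ]
        f <- (1 - w) * f + w * sf[p, ]
        m <- (1 - w) * m + w * sm[p, ]
      }
      list(a = g * a, f = g * f, m = g * m)
    })

    # activation profiles on both clocks
    act_emg <- matrix(cfg$emg_noise_floor, n_emg, EMG_CHANNELS)
    off_fmg <- matrix(0, n_low, FMG_CHANNELS)
    off_imu <- matrix(0, n_low, IMU_CHANNELS)
    for (c in seq_len(n_classes)) {
      t0 <- onsets[c]; t1 <- t0 + cfg$movement_duration_s
      eh <- block_envelope(t_emg, t0, t1, cfg$ramp_s)
      el <- block_envelope(t_low, t0, t1, cfg$ramp_s)
      nz <- which(eh > 0)
      if (length(nz) > 0) {
        act_emg[nz, ] <- act_emg[nz, ] + outer(eh[nz], sig[[c]]$a)
      }
      nzl <- which(el > 0)
      if (length(nzl) > 0) {
        off_fmg[nzl, ] <- off_fmg[nzl, ] + outer(el[nzl], sig[[c]]$f)
        off_imu[nzl, ] <- off_imu[nzl, ] + outer(el[nzl], sig[[c]]$m)
      }
    }

    emg <- matrix(0, n_emg, EMG_CHANNELS)
    for (j in seq_len(EMG_CHANNELS)) {
      emg[, j] <- cfg$emg_gain * act_emg[, j] *
        bandlimited_noise(n_emg, cfg$emg_band, EMG_RATE)
    }

    drift_phase <- stats::runif(FMG_CHANNELS, 0, 2 * pi)
    drift <- vapply(seq_len(FMG_CHANNELS), function(k) {
      cfg$fmg_drift_amp *
        sin(2 * pi * t_low / cfg$fmg_drift_period_s + drift_phase[k])
    }, numeric(n_low))
    fmg <- cfg$fmg_baseline + off_fmg + drift +
      matrix(stats::rnorm(n_low * FMG_CHANNELS, sd = cfg$sigma_fmg),
             n_low, FMG_CHANNELS)

    imu_base <- c(0, 0, 9.81, 0, 0, 0, 20, 0, 40, 0, 0, 0)
    imu <- matrix(imu_base, n_low, IMU_CHANNELS, byrow = TRUE) + off_imu +
      matrix(stats::rnorm(n_low * IMU_CHANNELS, sd = cfg$sigma_imu),
             n_low, IMU_CHANNELS)

    if (cfg$clip_fraction > 0) {
      n_clip <- stats::rbinom(1, n_low, cfg$clip_fraction)
      if (n_clip > 0) {
        idx <- sample.int(n_low, n_clip)
        ch <- sample.int(FMG_CHANNELS, n_clip, replace = TRUE)
        fmg[cbind(idx, ch)] <- cfg$fmg_valid_range[2] +
          abs(stats::rnorm(n_clip, 1))
      }
    }

    multimodal_recording(
      emg = emg, fmg = fmg, imu = imu,
      triggers = data.frame(onset_s = onsets, label = cfg$labels),
      subject_id = subject_id, trial_id = trial_id,
      fmg_valid_range = cfg$fmg_valid_range
    )
  })
}

#' Generate a synthetic cohort
#'
#' One subject per impairment profile, `cfg$n_trials` recordings each.
#' Per-recording seeds are derived deterministically from
#' `(cfg$seed, subject index, trial index)`, so regeneration with the same
#' master seed is byte-identical and subjects never share a noise stream.
#'
#' @param cfg A [synth_config()].
#' @param profiles List of [impairment_profile()]s (one subject each).
#' @param out_dir Optional directory: when given, each recording is also
#'   written as a session directory `S<subject>/trial<k>`.
#' @return List (one element per subject) of lists of
#'   `multimodal_recording`s, with the profile attached as attribute
#'   `"profile"`.
#' @export
generate_cohort <- function(cfg, profiles, out_dir = NULL) {
  if (length(profiles) < 1) stop("need at least one impairment profile",
                                 call. = FALSE)
  lapply(seq_along(profiles), function(s) {
    subject_id <- sprintf("S%02d", s)
    recs <- lapply(seq_len(cfg$n_trials), function(k) {
      rec <- generate_trial(cfg, profiles[[s]], trial_id = k,
                            subject_id = subject_id, subject_index = s)
      if (!is.null(out_dir)) {
        write_session(rec, file.path(out_dir, subject_id,
                                     sprintf("trial%02d", k)))
      }
      rec
    })
    attr(recs, "profile") <- profiles[[s]]
    attr(recs, "subject_id") <- subject_id
    recs
  })
}
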