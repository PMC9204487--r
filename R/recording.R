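#' Construct a multimodal recording
#'
#' Container for one synchronized trial of raw sensor streams: EMG (6
#' channels, volts, 1926 Hz), FMG barometric pressure (8 channels, arbitrary
#' calibrated units, 36 Hz), IMU (12 channels at 36 Hz: ax/ay/az in m/s^2,
#' gx/gy/gz in deg/s, mx/my/mz in uT, roll/pitch/yaw in deg), and a trigger
#' track of movement onsets. Time is seconds from stream start; sample
#' indices are 0-based and intervals half-open, which keeps multirate
#' alignment arithmetic free of off-by-one corrections.
#'
#' Validation enforces: channel counts; EMG and low-rate stream durations
#' consistent within one low-rate sample period; strictly increasing trigger
#' onsets inside `[0, duration]`; labels drawn from [movement_labels()];
#' `fmg_valid_range[1] < fmg_valid_range[2]`.
#'
#' @param emg Numeric matrix `[n_emg x 6]`, volts.
#' @param fmg Numeric matrix `[n_low x 8]`, calibrated pressure units.
#' @param imu Numeric matrix `[n_low x 12]`, columns ax..yaw.
#' @param triggers Data frame with columns `onset_s` (numeric seconds) and
#'   `label` (character, see [movement_labels()]); may have zero rows.
#' @param subject_id,trial_id Identifiers (character / integer-like).
#' @param fmg_valid_range Numeric length-2, the FMG sensor measuring range;
#'   samples outside it are treated as invalid by [drop_invalid_fmg()].
#' @param rates Named list `list(emg=, low=)`, Hz. Fixed by the hardware;
#'   exposed so that files carrying other rates are rejected loudly.
#' @return An object of class `multimodal_recording`.
#' @export
multimodal_recording <- function(emg, fmg, imu, triggers,
                                 subject_id = "S01", trial_id = 1L,
                                 fmg_valid_range = c(0, 115),
                                 rates = list(emg = EMG_RATE, low = LOW_RATE)) {
  emg <- as.matrix(emg); fmg <- as.matrix(fmg); imu <- as.matrix(imu)
  rec <- structure(
    list(emg = emg, fmg = fmg, imu = imu,
         triggers = as.data.frame(triggers),
         subject_id = as.character(subject_id),
         trial_id = as.integer(trial_id),
         fmg_valid_range = as.numeric(fmg_valid_range),
         rates = rates),
    class = "multimodal_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  if (ncol(rec$emg) != EMG_CHANNELS) {
    stop("emg stream must have ", EMG_CHANNELS, " channels, found ",
         ncol(rec$emg), call. = FALSE)
  }
  if (ncol(rec$fmg) != FMG_CHANNELS) {
    stop("fmg stream must have ", FMG_CHANNELS, " channels, found ",
         ncol(rec$fmg), call. = FALSE)
  }
  if (ncol(rec$imu) != IMU_CHANNELS) {
    stop("imu stream must have ", IMU_CHANNELS, " channels, found ",
         ncol(rec$imu), call. = FALSE)
  }
  if (nrow(rec$fmg) != nrow(rec$imu)) {
    stop("fmg and imu streams must share the low-rate clock (",
         nrow(rec$fmg), " vs ", nrow(rec$imu), " samples)", call. = FALSE)
  }
  dur_emg <- nrow(rec$emg) / rec$rates$emg
  dur_low <- nrow(rec$fmg) / rec$rates$low
  if (abs(dur_emg - dur_low) > 1 / rec$rates$low + 1e-9) {
    stop("emg (", signif(dur_emg, 6), " s) and low-rate (", signif(dur_low, 6),
         " s) stream durations disagree by more than one low-rate sample",
         call. = FALSE)
  }
  vr <- rec$fmg_valid_range
  if (length(vr) != 2 || !(vr[1] < vr[2])) {
    stop("fmg_valid_range must be (low, high) with low < high", call. = FALSE)
  }
  tr <- rec$triggers
  if (!all(c("onset_s", "label") %in% names(tr))) {
    stop("triggers must have columns onset_s and label", call. = FALSE)
  }
  if (nrow(tr) > 0) {
    if (any(diff(tr$onset_s) <= 0)) {
      stop("trigger onsets must be strictly increasing", call. = FALSE)
    }
    if (any(tr$onset_s < 0) || any(tr$onset_s > dur_low + 1 / rec$rates$low)) {
      stop("trigger onsets must lie within [0, duration]", call. = FALSE)
    }
    bad <- setdiff(unique(tr$label), movement_labels())
    if (length(bad) > 0) {
      stop("unknown movement labels in triggers: ",
           paste(bad, collapse = ","), call. = FALSE)
    }
  }
  invisible(rec)
}

#' @export
print.multimodal_recording <- function(x, ...) {
  cat("<multimodal_recording> subject", x$subject_id, "trial", x$trial_id, "\n")
  cat(sprintf("  emg: %d x %d @ %g Hz (%.2f s)\n", nrow(x$emg), ncol(x$emg),
              x$rates$emg, nrow(x$emg) / x$rates$emg))
  cat(sprintf("  fmg: %d x %d, imu: %d x %d @ %g Hz\n", nrow(x$fmg),
              ncol(x$fmg), nrow(x$imu), ncol(x$imu), x$rates$low))
  cat(sprintf("  triggers: %d (%s)\n", nrow(x$triggers),
              paste(utils::head(x$triggers$label, 12), collapse = " ")))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec A `multimodal_recording`.
#' @return Duration of the low-rate clock in seconds.
#' @export
recording_duration <- function(rec) nrow(rec$fmg) / rec$rates$low
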