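#' Gesture label set
#'
#' The fixed 12-gesture vocabulary: eleven activities-of-daily-living hand,
#' wrist and forearm movements drawn from the Fugl-Meyer Assessment plus a
#' designated no-motion rest class (`NM`). The order returned here is frozen
#' and used everywhere a class index appears (synthetic trial block order,
#' confusion-matrix rows, LDA class indices, tie-breaking).
#'
#' @return Character vector of the 12 label codes: mass flexion (MF), mass
#'   extension (ME), hook-like grasp (HG), thumb adduction (TA), opposition
#'   (O), cylinder grip (CG), spherical grip (SG), wrist volar flexion (WF),
#'   wrist dorsiflexion (WE), forearm pronation (FP), forearm supination (FS),
#'   no motion (NM).
#' @export
#' @examples
#' movement_labels()
movement_labels <- function() {
  c("MF", "ME", "HG", "TA", "O", "CG", "SG", "WF", "WE", "FP", "FS", "NM")
}

#' @rdname movement_labels
#' @export
rest_label <- function() "NM"

# channel-count constants; frozen by the sensor set
EMG_CHANNELS <- 6L
FMG_CHANNELS <- 8L
IMU_CHANNELS <- 12L
EMG_RATE <- 1926
LOW_RATE <- 36

imu_channel_names <- function() {
  c("ax", "ay", "az", "gx", "gy", "gz",
    "mx", "my", "mz", "roll", "pitch", "yaw")
}

#' Names of the 68 fused features in their frozen order
#'
#' The fused feature vector is laid out as: for each EMG channel 1..6 the
#' 8-tuple (MAV, WL, ZC, SSC, AR1..AR4) — 48 columns; then the MAV of each
#' FMG channel 1..8; then the MAV of each IMU channel (ax..yaw). This
#' ordering is frozen: column masks, importance rankings and serialized
#' models all refer to it.
#'
#' @return Character vector of length 68.
#' @export
feature_names <- function() {
  emg <- as.vector(vapply(seq_len(EMG_CHANNELS), function(j) {
    paste0("emg", j, "_", c("mav", "wl", "zc", "ssc", paste0("ar", 1:4)))
  }, character(8)))
  fmg <- paste0("fmg", seq_len(FMG_CHANNELS), "_mav")
  imu <- paste0("imu_", imu_channel_names(), "_mav")
  c(emg, fmg, imu)
}

#' Column mask for a sensor configuration
#'
#' Maps a non-empty subset of `{"EMG","FMG","IMU"}` to the column indices it
#' selects in the 68-dimensional fused feature vector (EMG: 48 columns,
#' FMG: 8, IMU: 12). The seven admissible subsets give mask sizes
#' 8, 12, 20, 48, 56, 60 and 68.
#'
#' @param sensors Character vector, non-empty subset of
#'   `c("EMG","FMG","IMU")` (case-insensitive).
#' @return Integer vector of column indices into the fused feature vector.
#' @export
#' @examples
#' length(sensor_mask(c("EMG", "FMG")))  # 56
sensor_mask <- function(sensors) {
  sensors <- toupper(sensors)
  bad <- setdiff(sensors, c("EMG", "FMG", "IMU"))
  if (length(bad) > 0 || length(sensors) == 0) {
    stop("sensors must be a non-empty subset of {EMG, FMG, IMU}; got: ",
         paste(sensors, collapse = ","), call. = FALSE)
  }
  idx <- integer(0)
  if ("EMG" %in% sensors) idx <- c(idx, 1:48)
  if ("FMG" %in% sensors) idx <- c(idx, 49:56)
  if ("IMU" %in% sensors) idx <- c(idx, 57:68)
  idx
}

#' All seven sensor configurations
#'
#' @return Named list of the 7 non-empty subsets of `{EMG, FMG, IMU}`, in
#'   the fixed order single, double, triple.
#' @export
sensor_configs <- function() {
  list(
    EMG = "EMG", FMG = "FMG", IMU = "IMU",
    `EMG+FMG` = c("EMG", "FMG"),
    `EMG+IMU` = c("EMG", "IMU"),
    `FMG+IMU` = c("FMG", "IMU"),
    `EMG+FMG+IMU` = c("EMG", "FMG", "IMU")
  )
}

# modality of each fused-feature column
feature_modality <- function(idx = seq_len(68L)) {
  mod <- c(rep("EMG", 48L), rep("FMG", 8L), rep("IMU", 12L))
  mod[idx]
}
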