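# Session directory format
# ------------------------
#   meta.json     {subject_id, trial_id, rates:{emg,low}, channels:{emg,fmg,imu},
#                  fmg_valid_range:[lo,hi]}
#   emg.csv       t,ch1..ch6
#   fmg.csv       t,ch1..ch8
#   imu.csv       t,ax,ay,az,gx,gy,gz,mx,my,mz,roll,pitch,yaw
#   triggers.csv  onset_s,label
# Floats are written with "%.9g" (9 significant digits, '.' separator, no
# locale), so writing the same recording twice is byte-identical and a
# read-back round-trips to the declared precision.

fmt_num <- function(x) sprintf("%.9g", x)

write_stream_csv <- function(mat, rate, path, colnames) {
  t <- (seq_len(nrow(mat)) - 1) / rate
  rows <- do.call(paste, c(list(fmt_num(t)),
                           lapply(seq_len(ncol(mat)),
                                  function(j) fmt_num(mat[, j])),
                           sep = ","))
  con <- file(path, open = "wb")  # binary: fixed \n line endings
  on.exit(close(con))
  writeLines(c(paste(c("t", colnames), collapse = ","), rows), con, sep = "\n")
  invisible(path)
}

#' Write a recording as a session directory
#'
#' Serializes a [multimodal_recording()] into the plain-text session layout
#' (`meta.json` plus one CSV per stream and a trigger CSV) readable by
#' [read_session()]. Numeric values are formatted with 9 significant digits
#' using a fixed C locale, so two writes of the same recording produce
#' byte-identical files.
#'
#' @param rec A validated `multimodal_recording`.
#' @param path Directory to create/populate.
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(rec, path) {
  validate_recording(rec)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create session directory: ", path,
                              call. = FALSE)
  meta <- list(
    subject_id = rec$subject_id,
    trial_id = rec$trial_id,
    rates = list(emg = rec$rates$emg, low = rec$rates$low),
    channels = list(emg = ncol(rec$emg), fmg = ncol(rec$fmg),
                    imu = ncol(rec$imu)),
    fmg_valid_range = rec$fmg_valid_range
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_stream_csv(rec$emg, rec$rates$emg, file.path(path, "emg.csv"),
                   paste0("ch", seq_len(ncol(rec$emg))))
  write_stream_csv(rec$fmg, rec$rates$low, file.path(path, "fmg.csv"),
                   paste0("ch", seq_len(ncol(rec$fmg))))
  write_stream_csv(rec$imu, rec$rates$low, file.path(path, "imu.csv"),
                   imu_channel_names())
  con <- file(file.path(path, "triggers.csv"), open = "wb")
  trig_rows <- character(0)
  if (nrow(rec$triggers) > 0) {
    trig_rows <- paste(fmt_num(rec$triggers$onset_s), rec$triggers$label,
                       sep = ",")
  }
  writeLines(c("onset_s,label", trig_rows), con, sep = "\n")
  close(con)
  invisible(path)
}

read_stream_csv <- function(path, expected_cols, what) {
  if (!file.exists(path)) {
    stop("session is missing ", basename(path), call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) - 1L != expected_cols) {
    stop(what, " stream has ", ncol(df) - 1L, " channels, expected ",
         expected_cols, " (", basename(path), ")", call. = FALSE)
  }
  as.matrix(df[, -1, drop = FALSE])
}

#' Read a session directory
#'
#' Parses and validates the session layout written by [write_session()].
#' Channel counts and rates are cross-checked against `meta.json`; trigger
#' monotonicity and stream-duration consistency are enforced by the
#' recording validator.
#'
#' @param path Session directory.
#' @return A validated `multimodal_recording`.
#' @export
read_session <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    stop("session is missing meta.json: ", path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  emg <- read_stream_csv(file.path(path, "emg.csv"), meta$channels$emg, "emg")
  fmg <- read_stream_csv(file.path(path, "fmg.csv"), meta$channels$fmg, "fmg")
  imu <- read_stream_csv(file.path(path, "imu.csv"), meta$channels$imu, "imu")
  tr <- utils::read.csv(file.path(path, "triggers.csv"),
                        colClasses = c("numeric", "character"))
  multimodal_recording(
    emg = emg, fmg = fmg, imu = imu, triggers = tr,
    subject_id = meta$subject_id, trial_id = meta$trial_id,
    fmg_valid_range = as.numeric(meta$fmg_valid_range),
    rates = list(emg = meta$rates$emg, low = meta$rates$low)
  )
}
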