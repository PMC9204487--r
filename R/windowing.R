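# Segmentation and multirate windowing
# ------------------------------------
# Sample indices are 0-based with half-open intervals [start, end) throughout;
# this keeps trigger arithmetic (round(onset * rate)) and the frame count
# closed form floor((L - win)/step) + 1 exact at both rates.

#' Windowing configuration
#'
#' EMG uses overlapped windows of 222 ms with a 55.6 ms step; FMG/IMU use
#' disjoint 55.6 ms windows. The derived integer sample counts are frozen:
#' at 1926 Hz, 222 ms -> 428 samples and 55.6 ms -> 107; at 36 Hz, 55.6 ms
#' -> 2 samples (round-half-up of 427.57, 107.09 and 2.0016; the rounded
#' counts are recorded here and reported in outputs).
#'
#' @param emg_window_s,emg_step_s Overlapped EMG windowing, seconds.
#' @param low_window_s Disjoint FMG/IMU window, seconds.
#' @param emg_rate,low_rate Sampling rates, Hz.
#' @return A `windowing_config` with derived counts `emg_win`, `emg_step`,
#'   `low_win`.
#' @export
windowing_config <- function(emg_window_s = 0.222, emg_step_s = 0.0556,
                             low_window_s = 0.0556,
                             emg_rate = EMG_RATE, low_rate = LOW_RATE) {
  w <- list(
    emg_window_s = emg_window_s, emg_step_s = emg_step_s,
    low_window_s = low_window_s,
    emg_rate = emg_rate, low_rate = low_rate,
    emg_win = as.integer(round(emg_window_s * emg_rate)),
    emg_step = as.integer(round(emg_step_s * emg_rate)),
    low_win = as.integer(round(low_window_s * low_rate))
  )
  if (w$emg_step > w$emg_win || w$emg_step < 1 || w$low_win < 1) {
    stop("windowing_config: need 1 <= emg_step <= emg_win and low_win >= 1",
         call. = FALSE)
  }
  structure(w, class = "windowing_config")
}

#' Trimming rule for movement segments
#'
#' The first `head_s` and last `tail_s` of each movement are removed before
#' feature extraction: transition bursts at movement boundaries inflate EMG
#' amplitude, and subjects are slow to initiate. Defaults (2 s head, 0.5 s
#' tail) leave 3.5 s of each 6 s movement.
#'
#' @param head_s,tail_s Seconds removed from segment start / end.
#' @return A `trim_rule`.
#' @export
trim_rule <- function(head_s = 2.0, tail_s = 0.5) {
  if (head_s < 0 || tail_s < 0) stop("trim durations must be >= 0",
                                     call. = FALSE)
  structure(list(head_s = head_s, tail_s = tail_s), class = "trim_rule")
}

new_segment <- function(label, emg_start, emg_end, low_start, low_end,
                        trial_id) {
  if (emg_end <= emg_start || low_end <= low_start) {
    stop("segment ranges must be non-empty", call. = FALSE)
  }
  structure(list(label = label,
                 emg_start = as.integer(emg_start),
                 emg_end = as.integer(emg_end),
                 low_start = as.integer(low_start),
                 low_end = as.integer(low_end),
                 trial_id = as.integer(trial_id)),
            class = "segment")
}

#' Segment a recording by its triggers
#'
#' One segment per trigger: the EMG range is
#' `[round(onset * 1926), round((onset + dur) * 1926))` and the low-rate
#' range the analogue at 36 Hz (0-based, half-open). Segments are truncated
#' at the recording end; a trigger at or beyond the end is dropped with a
#' warning.
#'
#' @param rec A `multimodal_recording`.
#' @param movement_duration_s Nominal movement duration, seconds.
#' @return List of `segment` objects (possibly empty).
#' @export
segment_by_triggers <- function(rec, movement_duration_s = 6) {
  stopifnot(movement_duration_s > 0)
  tr <- rec$triggers
  if (nrow(tr) == 0) return(list())
  n_emg <- nrow(rec$emg); n_low <- nrow(rec$fmg)
  segs <- list()
  for (i in seq_len(nrow(tr))) {
    on <- tr$onset_s[i]
    es <- round(on * rec$rates$emg)
    ee <- min(round((on + movement_duration_s) * rec$rates$emg), n_emg)
    ls <- round(on * rec$rates$low)
    le <- min(round((on + movement_duration_s) * rec$rates$low), n_low)
    if (es >= n_emg || ls >= n_low || ee <= es || le <= ls) {
      warning("dropping trigger ", tr$label[i], " at ", on,
              " s: beyond recording end", call. = FALSE)
      next
    }
    segs[[length(segs) + 1L]] <-
      new_segment(tr$label[i], es, ee, ls, le, rec$trial_id)
  }
  segs
}

#' Trim a segment's head and tail
#'
#' Shifts the segment boundaries by `round(head_s * rate)` /
#' `round(tail_s * rate)` samples on each stream's own clock.
#'
#' @param seg A `segment`.
#' @param rule A [trim_rule()].
#' @param wcfg A [windowing_config()] (supplies the rates).
#' @return The trimmed `segment`.
#' @export
trim_segment <- function(seg, rule = trim_rule(), wcfg = windowing_config()) {
  dur <- (seg$emg_end - seg$emg_start) / wcfg$emg_rate
  if (dur <= rule$head_s + rule$tail_s) {
    stop("segment of ", signif(dur, 4), " s too short to trim ",
         rule$head_s, " + ", rule$tail_s, " s", call. = FALSE)
  }
  new_segment(
    seg$label,
    seg$emg_start + round(rule$head_s * wcfg$emg_rate),
    seg$emg_end - round(rule$tail_s * wcfg$emg_rate),
    seg$low_start + round(rule$head_s * wcfg$low_rate),
    seg$low_end - round(rule$tail_s * wcfg$low_rate),
    seg$trial_id
  )
}

#' Mark out-of-range FMG samples
#'
#' Low-rate sample indices (0-based) where any FMG channel falls outside the
#' sensor's measuring range are marked as dropped; downstream, any frame
#' whose low-rate window intersects a dropped index is flagged `valid =
#' FALSE`. The recording itself is returned unchanged — deletion is realized
#' as frame invalidation, never as resampling.
#'
#' @param rec A `multimodal_recording` with `fmg_valid_range` set.
#' @return `list(rec = rec, dropped = integer 0-based low-rate indices)`.
#' @export
drop_invalid_fmg <- function(rec) {
  vr <- rec$fmg_valid_range
  bad <- which(apply(rec$fmg < vr[1] | rec$fmg > vr[2], 1, any))
  list(rec = rec, dropped = as.integer(bad - 1L))
}

#' Enumerate feature frames of a segment
#'
#' Frame `i` (0-based) covers EMG samples
#' `[start + i*step, start + i*step + win)`; the frame count is
#' `floor((L - win)/step) + 1` for a segment of `L` EMG samples. Each EMG
#' frame is paired with the latest complete disjoint low-rate window (within
#' the segment's low-rate range) whose end time does not exceed the EMG
#' window's end time — the multirate synchronization rule.
#'
#' @param seg A (trimmed) `segment`.
#' @param wcfg A [windowing_config()].
#' @return Data frame with 0-based half-open columns `emg_start`, `emg_end`,
#'   `low_start`, `low_end` and `t_end` (frame end time, seconds); zero rows
#'   (with a warning) if the segment is shorter than one EMG window.
#' @export
make_frames <- function(seg, wcfg = windowing_config()) {
  L <- seg$emg_end - seg$emg_start
  if (L < wcfg$emg_win) {
    warning("segment of ", L, " EMG samples shorter than one window (",
            wcfg$emg_win, "); no frames", call. = FALSE)
    return(data.frame(emg_start = integer(0), emg_end = integer(0),
                      low_start = integer(0), low_end = integer(0),
                      t_end = numeric(0)))
  }
  n <- (L - wcfg$emg_win) %/% wcfg$emg_step + 1L
  emg_start <- seg$emg_start + (seq_len(n) - 1L) * wcfg$emg_step
  emg_end <- emg_start + wcfg$emg_win
  t_end <- emg_end / wcfg$emg_rate
  # disjoint low-rate windows k: [low_start + k*w, low_start + (k+1)*w)
  w <- wcfg$low_win
  k_max_seg <- (seg$low_end - seg$low_start) %/% w - 1L
  k <- floor((t_end * wcfg$low_rate - seg$low_start) / w - 1 + 1e-9)
  k <- pmin(pmax(k, 0L), max(k_max_seg, 0L))
  low_start <- as.integer(seg$low_start + k * w)
  data.frame(emg_start = as.integer(emg_start),
             emg_end = as.integer(emg_end),
             low_start = low_start,
             low_end = low_start + w,
             t_end = t_end)
}
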