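# Time-domain features
# --------------------
# The classic sliding-window EMG feature set: mean absolute value (MAV),
# waveform length (WL), threshold zero crossings (ZC), threshold slope sign
# changes (SSC), plus fourth-order autoregressive (AR) coefficients. All
# internals operate column-wise on a window matrix [N x n_windows] so a
# whole trial's frames are featurized in a handful of vectorized passes.

#' Feature-extraction configuration
#'
#' @param zc_ssc_threshold Amplitude threshold `eps` for ZC and SSC, in the
#'   signal's units (volts for EMG; default 4e-6 V), rejecting noise-level
#'   crossings.
#' @param ar_order Autoregressive model order (default 4).
#' @param ar_method `"burg"` (default; stable on short 428-sample windows)
#'   or `"ls"` (least-squares fallback).
#' @return A `feature_config`.
#' @export
feature_config <- function(zc_ssc_threshold = 4e-6, ar_order = 4L,
                           ar_method = c("burg", "ls")) {
  if (zc_ssc_threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  if (ar_order < 1) stop("ar_order must be >= 1", call. = FALSE)
  structure(list(zc_ssc_threshold = zc_ssc_threshold,
                 ar_order = as.integer(ar_order),
                 ar_method = match.arg(ar_method)),
            class = "feature_config")
}

as_window_matrix <- function(w) {
  if (is.matrix(w)) w else matrix(w, ncol = 1L)
}

#' Mean absolute value
#'
#' `MAV = (1/N) * sum |x_i|` per channel.
#'
#' @param w Numeric vector (one channel) or matrix (channels in columns).
#' @return Numeric vector, one value per channel.
#' @export
mav <- function(w) {
  w <- as_window_matrix(w)
  if (nrow(w) < 1) stop("mav: empty window", call. = FALSE)
  colMeans(abs(w))
}

#' Waveform length
#'
#' `WL = sum |x_{i+1} - x_i|` per channel; zero iff the channel is constant.
#'
#' @inheritParams mav
#' @return Numeric vector, one value per channel.
#' @export
wl <- function(w) {
  w <- as_window_matrix(w)
  n <- nrow(w)
  if (n < 2) stop("wl: need at least 2 samples", call. = FALSE)
  colSums(abs(w[-1, , drop = FALSE] - w[-n, , drop = FALSE]))
}

#' Threshold zero crossings
#'
#' Counts indices `i` with `x_i * x_{i+1} < 0` and `|x_i - x_{i+1}| >= eps`.
#'
#' @inheritParams mav
#' @param eps Amplitude threshold (same units as `w`).
#' @return Integer count per channel, in `[0, N-1]`.
#' @export
zc <- function(w, eps = 4e-6) {
  w <- as_window_matrix(w)
  n <- nrow(w)
  if (n < 2) stop("zc: need at least 2 samples", call. = FALSE)
  a <- w[-n, , drop = FALSE]; b <- w[-1, , drop = FALSE]
  colSums((a * b < 0) & (abs(a - b) >= eps))
}

#' Threshold slope sign changes
#'
#' Counts interior indices `i` with `(x_i - x_{i-1}) * (x_i - x_{i+1}) > 0`
#' (a local extremum) and `max(|x_i - x_{i-1}|, |x_i - x_{i+1}|) >= eps`.
#'
#' @inheritParams zc
#' @return Integer count per channel, in `[0, N-2]`.
#' @export
ssc <- function(w, eps = 4e-6) {
  w <- as_window_matrix(w)
  n <- nrow(w)
  if (n < 3) stop("ssc: need at least 3 samples", call. = FALSE)
  d1 <- w[2:(n - 1), , drop = FALSE] - w[1:(n - 2), , drop = FALSE]
  d2 <- w[2:(n - 1), , drop = FALSE] - w[3:n, , drop = FALSE]
  colSums((d1 * d2 > 0) & (pmax(abs(d1), abs(d2)) >= eps))
}

# Burg recursion, vectorized over window columns. Convention matches
# stats::ar.burg: x_t - m = sum_p a_p (x_{t-p} - m) + e_t. Zero-variance
# columns get all-zero coefficients (flagged by the caller).
burg_many <- function(W, order = 4L) {
  N <- nrow(W); M <- ncol(W)
  if (N <= 2 * order) stop("burg: window too short for order ", order,
                           call. = FALSE)
  W <- W - matrix(colMeans(W), N, M, byrow = TRUE)
  f <- W; b <- W
  A <- matrix(0, order, M)
  for (p in seq_len(order)) {
    n <- nrow(f)
    fp <- f[-1, , drop = FALSE]
    bp <- b[-n, , drop = FALSE]
    den <- colSums(fp^2) + colSums(bp^2)
    k <- ifelse(den > 0, 2 * colSums(fp * bp) / den, 0)
    if (p > 1) {
      prev <- A[1:(p - 1), , drop = FALSE]
      A[1:(p - 1), ] <- prev -
        prev[(p - 1):1, , drop = FALSE] *
          matrix(k, p - 1, M, byrow = TRUE)
    }
    A[p, ] <- k
    kk <- matrix(k, n - 1, M, byrow = TRUE)
    fn <- fp - bp * kk
    b <- bp - fp * kk
    f <- fn
  }
  A
}

ls_ar_many <- function(W, order = 4L) {
  # conditional least squares per column; slower, kept as a fallback
  apply(W, 2, function(x) {
    x <- x - mean(x)
    if (stats::var(x) == 0) return(rep(0, order))
    n <- length(x)
    y <- x[(order + 1):n]
    X <- sapply(seq_len(order), function(p) x[(order + 1 - p):(n - p)])
    as.numeric(stats::coef(stats::lm.fit(X, y)))
  })
}

#' Autoregressive coefficients
#'
#' Fits `x_i = sum_p a_p x_{i-p} + e_i` (after demeaning) per channel and
#' returns `a_1..a_order`. The default estimator is the Burg recursion;
#' zero-variance channels return all-zero coefficients rather than failing
#' (the enclosing frame is flagged degenerate by [extract_features()]).
#'
#' @inheritParams mav
#' @param order Model order.
#' @param method `"burg"` or `"ls"` (conditional least squares).
#' @return Matrix `[order x n_channels]` of coefficients.
#' @export
ar_coeffs <- function(w, order = 4L, method = c("burg", "ls")) {
  method <- match.arg(method)
  w <- as_window_matrix(w)
  if (method == "burg") burg_many(w, order) else ls_ar_many(w, order)
}

# gather matrix of window columns from one channel: idx[i, f] = sample i of
# frame f (1-based)
gather_windows <- function(x, starts0, win) {
  idx <- outer(seq_len(win), starts0, `+`)  # starts0 are 0-based
  matrix(x[idx], nrow = win)
}

#' Extract the fused 68-dimensional feature matrix
#'
#' For every frame of every segment: 8 features per EMG channel (MAV, WL,
#' ZC, SSC, AR1..AR4) from the overlapped 428-sample window, then the MAV of
#' each FMG and IMU channel from the paired disjoint 2-sample window — 48 +
#' 8 + 12 = 68 features in the frozen [feature_names()] order. Frames whose
#' low-rate window intersects a dropped out-of-range FMG index are flagged
#' `valid = FALSE`; frames containing a zero-variance EMG channel are
#' flagged `degenerate = TRUE` with zero AR coefficients.
#'
#' @param rec A `multimodal_recording`.
#' @param segments List of (trimmed) `segment`s.
#' @param wcfg A [windowing_config()].
#' @param fcfg A [feature_config()].
#' @param dropped Integer 0-based low-rate indices from
#'   [drop_invalid_fmg()].
#' @return A `feature_matrix`: list with `x` (`[n x 68]`), `label`, `t`
#'   (frame end times, s), `valid`, `degenerate`, `trial_id`, `norm`
#'   (`NULL` until [zscore_by_trial()]).
#' @export
extract_features <- function(rec, segments, wcfg = windowing_config(),
                             fcfg = feature_config(),
                             dropped = integer(0)) {
  frames <- lapply(segments, make_frames, wcfg = wcfg)
  n_per <- vapply(frames, nrow, integer(1))
  n_tot <- sum(n_per)
  x <- matrix(0, n_tot, 68L, dimnames = list(NULL, feature_names()))
  label <- character(n_tot); t_end <- numeric(n_tot)
  valid <- rep(TRUE, n_tot); degen <- rep(FALSE, n_tot)
  trial <- rep(rec$trial_id, n_tot)
  dropped_set <- as.integer(dropped)
  off <- 0L
  for (si in seq_along(segments)) {
    fr <- frames[[si]]
    n <- nrow(fr)
    if (n == 0) next
    rows <- off + seq_len(n)
    eps <- fcfg$zc_ssc_threshold
    for (j in seq_len(EMG_CHANNELS)) {
      W <- gather_windows(rec$emg[, j], fr$emg_start, wcfg$emg_win)
      base <- (j - 1L) * 8L
      x[rows, base + 1L] <- mav(W)
      x[rows, base + 2L] <- wl(W)
      x[rows, base + 3L] <- zc(W, eps)
      x[rows, base + 4L] <- ssc(W, eps)
      sdz <- matrixStats_colVars(W) <= 0
      if (fcfg$ar_method == "burg") {
        ar <- burg_many(W, fcfg$ar_order)
      } else {
        ar <- ls_ar_many(W, fcfg$ar_order)
      }
      x[rows, base + 4L + seq_len(4L)] <- t(ar[seq_len(4L), , drop = FALSE])
      if (any(sdz)) degen[rows[sdz]] <- TRUE
    }
    for (k in seq_len(FMG_CHANNELS)) {
      W <- gather_windows(rec$fmg[, k], fr$low_start, wcfg$low_win)
      x[rows, 48L + k] <- mav(W)
    }
    for (m in seq_len(IMU_CHANNELS)) {
      W <- gather_windows(rec$imu[, m], fr$low_start, wcfg$low_win)
      x[rows, 56L + m] <- mav(W)
    }
    if (length(dropped_set) > 0) {
      hit <- vapply(seq_len(n), function(i) {
        any(dropped_set >= fr$low_start[i] & dropped_set < fr$low_end[i])
      }, logical(1))
      valid[rows[hit]] <- FALSE
    }
    label[rows] <- segments[[si]]$label
    t_end[rows] <- fr$t_end
    off <- off + n
  }
  structure(list(x = x, label = label, t = t_end, valid = valid,
                 degenerate = degen, trial_id = trial, norm = NULL),
            class = "feature_matrix")
}

# colVars without a matrixStats dependency
matrixStats_colVars <- function(W) {
  n <- nrow(W)
  (colSums(W^2) - colSums(W)^2 / n) / (n - 1)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix>", nrow(x$x), "frames x", ncol(x$x), "features;",
      sum(!x$valid), "invalid;",
      if (is.null(x$norm)) "raw" else "normalized", "\n")
  invisible(x)
}

#' Stack feature matrices
#'
#' @param fms List of `feature_matrix` objects (e.g. one per trial).
#' @return One combined `feature_matrix`.
#' @export
rbind_features <- function(fms) {
  structure(list(
    x = do.call(rbind, lapply(fms, `[[`, "x")),
    label = unlist(lapply(fms, `[[`, "label")),
    t = unlist(lapply(fms, `[[`, "t")),
    valid = unlist(lapply(fms, `[[`, "valid")),
    degenerate = unlist(lapply(fms, `[[`, "degenerate")),
    trial_id = unlist(lapply(fms, `[[`, "trial_id")),
    norm = if (all(!vapply(fms, function(f) is.null(f$norm), logical(1))))
      do.call(c, lapply(fms, `[[`, "norm")) else NULL
  ), class = "feature_matrix")
}

#' Per-trial zero-mean normalization
#'
#' Within each trial, every feature column is centered by the trial mean and
#' scaled by the trial standard deviation, matching the offline rule that
#' normalization statistics come from each respective trial. Columns with
#' `sd < 1e-12` are set to 0 (with a message). The applied statistics are
#' stored in `$norm` (one entry per trial), so normalization is invertible.
#'
#' @param fm A raw `feature_matrix` with at least 2 frames per trial.
#' @return The normalized `feature_matrix`.
#' @export
zscore_by_trial <- function(fm) {
  trials <- sort(unique(fm$trial_id))
  norm <- list()
  for (tr in trials) {
    rows <- which(fm$trial_id == tr)
    if (length(rows) < 2) {
      stop("trial ", tr, " has fewer than 2 frames; cannot normalize",
           call. = FALSE)
    }
    m <- colMeans(fm$x[rows, , drop = FALSE])
    s <- sqrt(matrixStats_colVars(fm$x[rows, , drop = FALSE]))
    flat <- s < 1e-12
    if (any(flat)) {
      message("trial ", tr, ": ", sum(flat),
              " constant feature column(s) set to 0")
      s[flat] <- 1
    }
    z <- (fm$x[rows, , drop = FALSE] -
            matrix(m, length(rows), 68L, byrow = TRUE)) /
      matrix(s, length(rows), 68L, byrow = TRUE)
    z[, flat] <- 0
    fm$x[rows, ] <- z
    norm[[as.character(tr)]] <- list(center = m, scale = s, constant = flat)
  }
  fm$norm <- norm
  fm
}

#' Undo per-trial normalization
#'
#' @param fm A `feature_matrix` normalized by [zscore_by_trial()].
#' @return The raw-scale `feature_matrix` (`norm` cleared). Columns that
#'   were constant are restored to their stored trial mean.
#' @export
denormalize <- function(fm) {
  if (is.null(fm$norm)) stop("feature matrix is not normalized",
                             call. = FALSE)
  for (tr in names(fm$norm)) {
    rows <- which(fm$trial_id == as.integer(tr))
    st <- fm$norm[[tr]]
    raw <- fm$x[rows, , drop = FALSE] *
      matrix(st$scale, length(rows), 68L, byrow = TRUE) +
      matrix(st$center, length(rows), 68L, byrow = TRUE)
    raw[, st$constant] <- matrix(st$center[st$constant], length(rows),
                                 sum(st$constant), byrow = TRUE)
    fm$x[rows, ] <- raw
  }
  fm$norm <- NULL
  fm
}
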