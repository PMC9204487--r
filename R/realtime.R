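# Grouped simulated real-time protocol
# ------------------------------------
# Offline training frames come from the [2 s, 5.5 s] span of each movement
# (head/tail trimming); the simulated real-time test takes the first 10
# frames starting 1 s into the held-out trial's movement and resolves them
# into a single decision by 10-frame majority voting, with the model
# restricted to the movement's game group.

#' Real-time protocol parameters
#'
#' @param train_head_s,train_tail_s Training-span trimming per movement
#'   (defaults 2 and 0.5 s: the `[2, 5.5]` s span of a 6 s movement).
#' @param test_offset_s Test frames start this long after movement onset
#'   (default 1 s, the reaction window granted in the games).
#' @param vote_window Frames per voted decision (default 10).
#' @return A `realtime_protocol`.
#' @export
realtime_protocol <- function(train_head_s = 2.0, train_tail_s = 0.5,
                              test_offset_s = 1.0, vote_window = 10L) {
  if (vote_window < 1) stop("vote_window must be >= 1", call. = FALSE)
  structure(list(train_head_s = train_head_s, train_tail_s = train_tail_s,
                 test_offset_s = test_offset_s,
                 vote_window = as.integer(vote_window)),
            class = "realtime_protocol")
}

# first `n_frames` frames starting `offset_s` into each movement
realtime_test_features <- function(rec, wcfg, fcfg, movement_duration_s,
                                   protocol) {
  segs <- segment_by_triggers(rec, movement_duration_s)
  segs <- lapply(segs, trim_segment,
                 rule = trim_rule(protocol$test_offset_s, 0), wcfg = wcfg)
  dropped <- drop_invalid_fmg(rec)$dropped
  fm <- extract_features(rec, segs, wcfg, fcfg, dropped = dropped)
  # keep the first vote_window frames of each movement
  keep <- unlist(lapply(split(seq_along(fm$label),
                              factor(fm$label, levels = unique(fm$label))),
                        utils::head, protocol$vote_window))
  keep <- sort(keep)
  fm$x <- fm$x[keep, , drop = FALSE]
  fm$label <- fm$label[keep]; fm$t <- fm$t[keep]
  fm$valid <- fm$valid[keep]; fm$degenerate <- fm$degenerate[keep]
  fm$trial_id <- fm$trial_id[keep]
  fm
}

#' Extract per-trial offline and real-time feature sets for one subject
#'
#' Convenience wrapper: segments each recording by its triggers, trims to
#' the training span, extracts the fused features, and also extracts the
#' real-time test frames per the protocol. Computing this once per subject
#' lets [loto_cv()], [ablate_sensors()] and [simulate_realtime()] share the
#' same features.
#'
#' @param recs List of `multimodal_recording`s (one per trial).
#' @param movement_duration_s Movement block duration, seconds.
#' @param wcfg,fcfg Windowing / feature configuration.
#' @param protocol A [realtime_protocol()].
#' @return `list(offline = feature_matrix over all trials, realtime = list
#'   of per-trial feature_matrix)`.
#' @export
subject_features <- function(recs, movement_duration_s = 6,
                             wcfg = windowing_config(),
                             fcfg = feature_config(),
                             protocol = realtime_protocol()) {
  rule <- trim_rule(protocol$train_head_s, protocol$train_tail_s)
  offline <- lapply(recs, function(rec) {
    segs <- segment_by_triggers(rec, movement_duration_s)
    segs <- lapply(segs, trim_segment, rule = rule, wcfg = wcfg)
    extract_features(rec, segs, wcfg, fcfg,
                     dropped = drop_invalid_fmg(rec)$dropped)
  })
  realtime <- lapply(recs, realtime_test_features, wcfg = wcfg, fcfg = fcfg,
                     movement_duration_s = movement_duration_s,
                     protocol = protocol)
  list(offline = rbind_features(offline), realtime = realtime)
}

# pooled mean/sd over the raw training frames; the streaming stand-in for
# per-trial statistics, which are acausal mid-stream
pooled_norm_stats <- function(x) {
  s <- sqrt(matrixStats_colVars(x))
  s[s < 1e-12] <- 1
  list(center = colMeans(x), scale = s)
}

apply_norm <- function(x, st) {
  (x - matrix(st$center, nrow(x), ncol(x), byrow = TRUE)) /
    matrix(st$scale, nrow(x), ncol(x), byrow = TRUE)
}

#' Simulated real-time classification with movement grouping
#'
#' Cross-validates the in-game protocol over trials: for each held-out
#' trial and each group of the grouping scheme, a group-restricted LDA model
#' is trained on the other trials' training-span frames (per-trial
#' normalized); each of the group's movements in the held-out trial is then
#' tested with its first `vote_window` frames (starting `test_offset_s`
#' after onset, normalized with statistics pooled from the training trials —
#' per-trial statistics are unavailable mid-stream) and resolved into one
#' majority-vote decision. Every movement contributes exactly one decision
#' per fold.
#'
#' @param subject Either a list of `multimodal_recording`s or the
#'   precomputed structure from [subject_features()].
#' @param grouping A [grouping_scheme()].
#' @param protocol A [realtime_protocol()].
#' @param movement_duration_s Movement duration, seconds (used only when
#'   `subject` holds raw recordings).
#' @param lambda LDA shrinkage.
#' @return List: `group_accuracy` (named, one per group), `accuracy` (mean
#'   over groups), `decisions` (data frame of every voted decision:
#'   fold, group, true, voted).
#' @export
simulate_realtime <- function(subject, grouping = grouping_scheme(),
                              protocol = realtime_protocol(),
                              movement_duration_s = 6, lambda = 1e-3) {
  if (!is.null(subject$offline)) sf <- subject
  else sf <- subject_features(subject, movement_duration_s,
                              protocol = protocol)
  groups <- grouping$groups
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each group needs at least 2 labels", call. = FALSE)
  }
  trials <- sort(unique(sf$offline$trial_id))
  if (length(trials) < 2) stop("need >= 2 trials", call. = FALSE)
  fmz <- zscore_by_trial(sf$offline)
  rt_by_trial <- sf$realtime
  rt_trial_ids <- vapply(rt_by_trial, function(f) f$trial_id[1], numeric(1))
  dec <- list()
  for (fi in seq_along(trials)) {
    held <- trials[fi]
    tr_rows <- which(fmz$trial_id != held & fmz$valid)
    raw_tr_rows <- which(sf$offline$trial_id != held & sf$offline$valid)
    st <- pooled_norm_stats(sf$offline$x[raw_tr_rows, , drop = FALSE])
    rt <- rt_by_trial[[which(rt_trial_ids == held)]]
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      rows <- tr_rows[fmz$label[tr_rows] %in% g]
      fit <- fit_lda(fmz$x[rows, , drop = FALSE], fmz$label[rows],
                     lambda = lambda)
      for (lab in g) {
        sel <- which(rt$label == lab)
        if (length(sel) == 0) next
        xte <- apply_norm(rt$x[sel, , drop = FALSE], st)
        pr <- predict_lda(fit, xte)
        voted <- majority_vote(pr$label, pr$scores, valid = rt$valid[sel])
        dec[[length(dec) + 1L]] <- data.frame(
          fold = held, group = gi, true = lab, voted = voted)
      }
    }
  }
  dec <- do.call(rbind, dec)
  grp_acc <- vapply(seq_along(groups), function(gi) {
    d <- dec[dec$group == gi, ]
    mean(d$voted == d$true)
  }, numeric(1))
  names(grp_acc) <- vapply(groups, paste, character(1), collapse = "+")
  list(group_accuracy = grp_acc, accuracy = mean(grp_acc), decisions = dec)
}
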