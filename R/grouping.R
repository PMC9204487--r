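# Movement grouping for the game rounds
# -------------------------------------
# During real-time play the 12 gestures are partitioned into small
# per-round groups so that gestures known to be mutually confusable never
# compete within one decision. The constraint list encodes the pairs
# observed to be misclassified with each other: CG<->SG, TA<->O, ME->HG,
# HG->MF, HG->NM, TA->NM, WE<->FP.

#' Pairs of gestures that must not share a group
#' @return List of length-2 character vectors.
#' @export
confusable_pairs <- function() {
  list(c("CG", "SG"), c("TA", "O"), c("ME", "HG"), c("HG", "MF"),
       c("HG", "NM"), c("TA", "NM"), c("WE", "FP"))
}

#' Grouping scheme
#'
#' Default: four groups of three satisfying every confusable-pair
#' constraint. Any alternative partition of the 12 labels can be supplied;
#' it is validated on construction.
#'
#' @param groups List of character vectors partitioning
#'   [movement_labels()].
#' @return A `grouping_scheme`.
#' @export
grouping_scheme <- function(groups = list(c("MF", "TA", "WE"),
                                          c("ME", "CG", "FP"),
                                          c("HG", "O", "FS"),
                                          c("SG", "WF", "NM"))) {
  g <- structure(list(groups = groups), class = "grouping_scheme")
  rep <- validate_grouping(g)
  if (!rep$valid) {
    stop("invalid grouping: ", paste(rep$violations, collapse = "; "),
         call. = FALSE)
  }
  g
}

#' Validate a grouping scheme
#'
#' Checks that the groups are disjoint, cover all 12 labels, and contain no
#' confusable pair; optionally scores the grouping against a confusion
#' matrix by the total within-group off-diagonal confusion mass (lower is
#' better).
#'
#' @param grouping A `grouping_scheme` or bare list of label vectors.
#' @param confusion Optional `confusion_matrix` to score against.
#' @return `list(valid, violations, within_group_confusion)`.
#' @export
validate_grouping <- function(grouping, confusion = NULL) {
  groups <- if (inherits(grouping, "grouping_scheme")) grouping$groups
            else grouping
  all_lab <- unlist(groups)
  violations <- character(0)
  if (anyDuplicated(all_lab)) {
    violations <- c(violations, paste("duplicated label(s):",
      paste(unique(all_lab[duplicated(all_lab)]), collapse = ",")))
  }
  missing <- setdiff(movement_labels(), all_lab)
  extra <- setdiff(all_lab, movement_labels())
  if (length(missing) > 0) {
    violations <- c(violations,
                    paste("missing label(s):", paste(missing, collapse = ",")))
  }
  if (length(extra) > 0) {
    violations <- c(violations,
                    paste("unknown label(s):", paste(extra, collapse = ",")))
  }
  for (pair in confusable_pairs()) {
    for (g in groups) {
      if (all(pair %in% g)) {
        violations <- c(violations,
                        paste0("confusable pair {", pair[1], ",", pair[2],
                               "} share a group"))
      }
    }
  }
  score <- NULL
  if (!is.null(confusion)) score <- within_group_confusion(groups, confusion)
  list(valid = length(violations) == 0, violations = violations,
       within_group_confusion = score)
}

#' Within-group off-diagonal confusion mass of a grouping
#'
#' @param groups List of label vectors.
#' @param confusion A `confusion_matrix` (or plain labeled matrix).
#' @return Total off-diagonal confusion counts between labels that share a
#'   group.
#' @export
within_group_confusion <- function(groups, confusion) {
  m <- unclass(confusion)
  tot <- 0
  for (g in groups) {
    g <- intersect(g, rownames(m))
    if (length(g) < 2) next
    sub <- m[g, g, drop = FALSE]
    tot <- tot + sum(sub) - sum(diag(sub))
  }
  tot
}

#' Greedy grouping from a confusion matrix
#'
#' Builds a partition into groups of the given sizes by repeatedly adding to
#' the current group the label with the least confusion mass against the
#' labels already in it (symmetrized counts). A cheap heuristic for
#' proposing groupings that keep mutually confusable gestures apart.
#'
#' @param confusion A `confusion_matrix` over the labels to partition.
#' @param group_sizes Integer vector summing to the number of labels
#'   (default four groups of three).
#' @return List of label vectors.
#' @export
greedy_grouping <- function(confusion, group_sizes = rep(3L, 4L)) {
  m <- unclass(confusion)
  labs <- rownames(m)
  stopifnot(sum(group_sizes) == length(labs))
  sym <- m + t(m); diag(sym) <- 0
  remaining <- labs
  groups <- list()
  for (gs in group_sizes) {
    # seed with the remaining label carrying the largest total confusion:
    # hardest labels get first pick of compatible partners
    tot <- rowSums(sym[remaining, remaining, drop = FALSE])
    g <- remaining[which.max(tot)]
    remaining <- setdiff(remaining, g)
    while (length(g) < gs) {
      cost <- vapply(remaining, function(l) sum(sym[l, g]), numeric(1))
      pick <- remaining[which.min(cost)]
      g <- c(g, pick)
      remaining <- setdiff(remaining, pick)
    }
    groups[[length(groups) + 1L]] <- g
  }
  groups
}
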