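## Segmentation accuracy evaluation: object matching by intersection-over-
## union at a threshold, and precision/recall/F1 reporting with per-batch
## mean +/- s.e.m.

#' Intersection over union (Jaccard index) of two pixel sets
#'
#' `|a intersect b| / (|a| + |b| - |a intersect b|)`. Pixel sets are vectors
#' of linear pixel indices into a common grid (see [maskPixelSets()]).
#' Disjoint sets score 0; two empty sets are rejected.
#'
#' @param a,b integer vectors of pixel indices.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) && !length(b)) stop("IoU of two empty pixel sets is undefined")
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

#' Match predicted to ground-truth objects at an IoU threshold
#'
#' A predicted/ground-truth pair is eligible iff its IoU is strictly greater
#' than `t`. Among eligible pairs a one-to-one matching is computed that
#' maximizes the number of matches (augmenting-path maximum-cardinality
#' bipartite matching); candidate pairs are examined in order of descending
#' IoU, then ascending (gt label, pred label), which fixes ties. Matched
#' pairs are true positives; unmatched predictions are false positives and
#' unmatched ground-truth objects false negatives. At `t >= 0.5` the
#' matching is unique regardless (an object can exceed 0.5 IoU with at most
#' one partner); the maximum-cardinality rule matters only for small `t`.
#'
#' @param pred,gt [LabelMask-class] objects of identical shape.
#' @param t IoU threshold in `(0, 1]`; the criterion is strict (`IoU > t`).
#' @return A `MatchResult`: list with `threshold`, `matches` (data.frame
#'   `pred_label`, `gt_label`, `iou`), `TP`, `FP`, `FN`, `n_pred`, `n_gt`.
#' @examples
#' m <- LabelMask(matrix(c(0L, 1L, 1L, 0L), 2, 2), 1)
#' matchObjects(m, m, t = 0.7)$TP
#' @export
matchObjects <- function(pred, gt, t = 0.7) {
  stopifnot(is(pred, "LabelMask"), is(gt, "LabelMask"))
  if (!all(dim(pred) == dim(gt))) stop("pred and gt masks differ in shape")
  stopifnot(t > 0, t <= 1)
  p <- maskLabels(pred); g <- maskLabels(gt)
  p_ids <- objectIds(pred); g_ids <- objectIds(gt)
  n_pred <- length(p_ids); n_gt <- length(g_ids)
  empty <- data.frame(pred_label = integer(), gt_label = integer(),
                      iou = numeric())
  pairs <- empty
  if (n_pred && n_gt) {
    both <- p > 0L & g > 0L
    if (any(both)) {
      ov <- table(p[both], g[both])
      sp <- table(factor(p[p > 0L], levels = p_ids))
      sg <- table(factor(g[g > 0L], levels = g_ids))
      nz <- which(ov > 0, arr.ind = TRUE)
      pl <- as.integer(rownames(ov))[nz[, 1L]]
      gl <- as.integer(colnames(ov))[nz[, 2L]]
      inter <- ov[nz]
      ious <- inter / (as.numeric(sp[as.character(pl)]) +
                       as.numeric(sg[as.character(gl)]) - inter)
      keep <- ious > t
      pairs <- data.frame(pred_label = pl[keep], gt_label = gl[keep],
                          iou = ious[keep])
      pairs <- pairs[order(-pairs$iou, pairs$gt_label, pairs$pred_label), ,
                     drop = FALSE]
    }
  }
  matched <- maxCardinalityMatch(pairs)
  res <- list(threshold = t, matches = matched,
              TP = nrow(matched), FP = n_pred - nrow(matched),
              FN = n_gt - nrow(matched), n_pred = n_pred, n_gt = n_gt)
  class(res) <- "MatchResult"
  res
}

#' Maximum-cardinality one-to-one matching over eligible pairs
#'
#' Greedy pass in the supplied (IoU-sorted) order, then Kuhn augmenting
#' paths to guarantee maximum cardinality. Deterministic for a fixed pair
#' ordering.
#' @noRd
maxCardinalityMatch <- function(pairs) {
  if (!nrow(pairs)) return(pairs[0L, , drop = FALSE])
  preds <- unique(pairs$pred_label)
  gts <- unique(pairs$gt_label)
  adj <- split(match(pairs$gt_label, gts), match(pairs$pred_label, preds))
  match_g <- rep(NA_integer_, length(gts))   # gt -> pred index
  match_p <- rep(NA_integer_, length(preds)) # pred -> gt index
  ## greedy seed in sorted order
  for (r in seq_len(nrow(pairs))) {
    pi <- match(pairs$pred_label[r], preds)
    gi <- match(pairs$gt_label[r], gts)
    if (is.na(match_p[pi]) && is.na(match_g[gi])) {
      match_p[pi] <- gi; match_g[gi] <- pi
    }
  }
  ## augment (seen lives in this frame; recursion updates it via <<-)
  seen <- logical(length(gts))
  try_augment <- function(pi) {
    for (gi in adj[[as.character(pi)]]) {
      if (seen[gi]) next
      seen[gi] <<- TRUE
      if (is.na(match_g[gi]) || try_augment(match_g[gi])) {
        match_g[gi] <<- pi
        match_p[pi] <<- gi
        return(TRUE)
      }
    }
    FALSE
  }
  for (pi in seq_along(preds)) {
    if (!is.na(match_p[pi])) next
    seen <- logical(length(gts))
    try_augment(pi)
  }
  keep <- !is.na(match_p)
  out <- data.frame(pred_label = preds[keep],
                    gt_label = gts[match_p[keep]])
  key <- paste(pairs$pred_label, pairs$gt_label)
  out$iou <- pairs$iou[match(paste(out$pred_label, out$gt_label), key)]
  out <- out[order(out$gt_label, out$pred_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Precision, recall and F1 from a match result
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`. Degenerate 0/0
#' cases: precision (recall) is 1 when its denominator is 0; F1 is 1 only
#' when both masks are empty, and 0 otherwise when TP = 0.
#'
#' @param m a `MatchResult` from [matchObjects()].
#' @return list with `precision`, `recall`, `f1`.
#' @export
f1Scores <- function(m) {
  stopifnot(inherits(m, "MatchResult"))
  tp <- m$TP; fp <- m$FP; fn <- m$FN
  precision <- if (tp + fp == 0L) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 1 else tp / (tp + fn)
  f1 <- if (tp == 0L) {
    if (fp == 0L && fn == 0L) 1 else 0
  } else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Evaluate a batch of mask pairs
#'
#' Per-image precision/recall/F1 plus the mean F1 and its standard error
#' (s.d. / sqrt(n) over images), the across-image reporting convention used
#' for segmentation benchmarks.
#'
#' @param pairs non-empty list, each element `list(pred = , gt = )` of
#'   [LabelMask-class] objects.
#' @param t IoU threshold.
#' @return list with `per_image` (data.frame), `mean_f1`, `sem_f1`, `n`.
#' @export
evaluateBatch <- function(pairs, t = 0.7) {
  if (!length(pairs)) stop("empty batch")
  per <- do.call(rbind, lapply(pairs, function(pr) {
    s <- f1Scores(matchObjects(pr$pred, pr$gt, t))
    data.frame(precision = s$precision, recall = s$recall, f1 = s$f1)
  }))
  rownames(per) <- NULL
  n <- nrow(per)
  sem <- if (n > 1L) stats::sd(per$f1) / sqrt(n) else 0
  list(per_image = per, mean_f1 = mean(per$f1), sem_f1 = sem, n = n)
}

#' @export
print.MatchResult <- function(x, ...) {
  cat(sprintf("MatchResult @ IoU > %.2f: TP %d, FP %d, FN %d (pred %d, gt %d)\n",
              x$threshold, x$TP, x$FP, x$FN, x$n_pred, x$n_gt))
  invisible(x)
}
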