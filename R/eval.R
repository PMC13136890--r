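# Site-level detection benchmarking: AUROC (mid-rank Mann-Whitney), AUPRC
# (step-wise average precision), thresholded confusion matrices, and
# proximity attribution of false positives to nearby true sites.

#' Scored positions with ground-truth labels
#'
#' Positive labels are the exact modified positions; neighbours count as
#' negatives (proximity attribution is provided separately as a post-hoc
#' explanation device, not label smoothing). Positions with `NA` scores are
#' flagged undefined and excluded from every metric.
#'
#' @param positions Integer vector of 1-based positions.
#' @param scores Numeric scores (total variation percentage, energy distance,
#'   ...); `NA` marks undefined positions.
#' @param truth A [ground_truth()] or integer vector of modified positions.
#' @return A data.frame of class `scored_positions` with columns `position`,
#'   `score`, `label`, `defined`.
#' @export
scored_positions <- function(positions, scores, truth) {
  if (inherits(truth, "ground_truth")) truth <- truth$position
  truth <- as.integer(truth)
  if (length(positions) != length(scores)) {
    stop("`positions` and `scores` must have equal length", call. = FALSE)
  }
  out <- data.frame(position = as.integer(positions),
                    score = as.numeric(scores),
                    label = as.integer(positions %in% truth),
                    defined = !is.na(scores))
  class(out) <- c("scored_positions", "data.frame")
  out
}

#' @noRd
.defined_split <- function(sp) {
  stopifnot(inherits(sp, "scored_positions"))
  d <- sp[sp$defined, , drop = FALSE]
  if (!any(d$label == 1L) || !any(d$label == 0L)) {
    stop("need at least one positive and one negative defined position",
         call. = FALSE)
  }
  d
}

#' Area under the ROC curve (mid-rank Mann-Whitney)
#'
#' `P(score+ > score-) + 0.5 P(tie)`, computed from mid-ranks; invariant
#' under strictly monotone transforms of the scores.
#'
#' @param sp A [scored_positions()].
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(sp) {
  d <- .defined_split(sp)
  r <- rank(d$score, ties.method = "average")
  n1 <- sum(d$label == 1L)
  n0 <- sum(d$label == 0L)
  (sum(r[d$label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: positions are ranked by descending score and
#' precision is accumulated at each recall step, with tied scores handled as
#' a single threshold group. No interpolation is applied.
#'
#' @param sp A [scored_positions()].
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(sp) {
  d <- .defined_split(sp)
  n_pos <- sum(d$label == 1L)
  thresholds <- sort(unique(d$score), decreasing = TRUE)
  ap <- 0
  prev_recall <- 0
  for (t in thresholds) {
    pred <- d$score >= t
    tp <- sum(pred & d$label == 1L)
    prec <- tp / sum(pred)
    recall <- tp / n_pos
    ap <- ap + (recall - prev_recall) * prec
    prev_recall <- recall
  }
  ap
}

#' Confusion matrix at a score threshold
#'
#' Scores `>= threshold` are predicted positive (ties at the threshold call
#' positive); counts run over defined positions only.
#'
#' @param sp A [scored_positions()].
#' @param threshold Finite numeric threshold.
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion_at <- function(sp, threshold) {
  stopifnot(inherits(sp, "scored_positions"), is.finite(threshold))
  d <- sp[sp$defined, , drop = FALSE]
  pred <- d$score >= threshold
  c(tp = sum(pred & d$label == 1L),
    fp = sum(pred & d$label == 0L),
    tn = sum(!pred & d$label == 0L),
    fn = sum(!pred & d$label == 1L))
}

#' Attribute false positives to nearby true modified sites
#'
#' A false-positive position is attributed when its distance to the nearest
#' true site is at most `window` nt (centered interpretation of a k-mer
#' window around the modification).
#'
#' @param fp_positions Integer vector of false-positive positions.
#' @param truth A [ground_truth()] or integer vector of true positions.
#' @param window Maximum distance in nt (default 7).
#' @return A list with `attributed` / `unattributed` position vectors and
#'   counts `n_attributed` / `n_unattributed`.
#' @export
proximity_attribution <- function(fp_positions, truth, window = 7) {
  if (inherits(truth, "ground_truth")) truth <- truth$position
  stopifnot(window >= 0)
  fp_positions <- as.integer(fp_positions)
  if (any(fp_positions %in% truth)) {
    stop("false-positive positions must not coincide with truth positions",
         call. = FALSE)
  }
  if (!length(truth)) {
    return(list(attributed = integer(), unattributed = fp_positions,
                n_attributed = 0L,
                n_unattributed = length(fp_positions)))
  }
  near <- vapply(fp_positions,
                 function(p) min(abs(p - truth)) <= window, logical(1))
  list(attributed = fp_positions[near],
       unattributed = fp_positions[!near],
       n_attributed = sum(near),
       n_unattributed = sum(!near))
}

#' Summary detection metrics for one score track
#'
#' @param sp A [scored_positions()].
#' @param threshold Optional threshold at which a confusion matrix and
#'   false-positive proximity attribution are added.
#' @param window Attribution window passed to [proximity_attribution()].
#' @return A list with `auroc`, `auprc`, `n_pos`, `n_neg`, and, when
#'   `threshold` is given, `confusion` and `attribution`.
#' @export
evaluate_scores <- function(sp, threshold = NULL, window = 7) {
  d <- .defined_split(sp)
  out <- list(auroc = auroc(sp), auprc = auprc(sp),
              n_pos = sum(d$label == 1L), n_neg = sum(d$label == 0L))
  if (!is.null(threshold)) {
    cm <- confusion_at(sp, threshold)
    fp <- d$position[d$score >= threshold & d$label == 0L]
    out$confusion <- as.list(cm)
    out$attribution <- proximity_attribution(
      fp, d$position[d$label == 1L], window = window)[
        c("n_attributed", "n_unattributed")]
  }
  out
}
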