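#' Match predicted objects to ground-truth objects by IoU
#'
#' One-to-one greedy matching: all (ground truth, prediction) pairs with
#' intersection-over-union at or above the threshold are considered in
#' descending IoU order (ties broken by ground-truth then predicted label),
#' and each object participates in at most one match. Matched pairs are true
#' positives; unmatched predictions are false positives and unmatched
#' ground-truth objects false negatives.
#'
#' @param gt,pred Integer label matrices of the same shape (0 = background).
#' @param iou_threshold Minimum IoU for a candidate match (default 0.5).
#' @return A `detection_match`: list with `pairs` (tibble of gt_label,
#'   pred_label, iou), counts `n_tp`, `n_fp`, `n_fn`, `n_gt`, `n_pred`, and
#'   `iou_threshold`.
#' @export
match_objects <- function(gt, pred, iou_threshold = 0.5) {
  stopifnot(is.matrix(gt), is.matrix(pred))
  if (!identical(dim(gt), dim(pred))) {
    stop("`gt` and `pred` must share the same shape.", call. = FALSE)
  }
  gt_labs <- setdiff(unique(as.integer(gt)), 0L)
  pr_labs <- setdiff(unique(as.integer(pred)), 0L)
  n_gt <- length(gt_labs)
  n_pred <- length(pr_labs)
  gt_area <- tabulate(gt[gt > 0L], nbins = max(gt, 0L))
  pr_area <- tabulate(pred[pred > 0L], nbins = max(pred, 0L))

  both <- gt > 0L & pred > 0L
  pairs <- tibble::tibble(gt_label = integer(0), pred_label = integer(0),
                          iou = numeric(0))
  if (any(both)) {
    ov <- tibble::tibble(gt_label = as.integer(gt[both]),
                         pred_label = as.integer(pred[both]))
    ov <- dplyr::count(ov, .data$gt_label, .data$pred_label, name = "inter")
    ov$iou <- ov$inter /
      (gt_area[ov$gt_label] + pr_area[ov$pred_label] - ov$inter)
    cand <- ov[ov$iou >= iou_threshold, , drop = FALSE]
    cand <- cand[order(-cand$iou, cand$gt_label, cand$pred_label), , drop = FALSE]
    used_gt <- logical(max(gt, 0L))
    used_pr <- logical(max(pred, 0L))
    take <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      g <- cand$gt_label[i]; p <- cand$pred_label[i]
      if (!used_gt[g] && !used_pr[p]) {
        used_gt[g] <- TRUE; used_pr[p] <- TRUE; take[i] <- TRUE
      }
    }
    pairs <- cand[take, c("gt_label", "pred_label", "iou"), drop = FALSE]
  }
  structure(
    list(pairs = pairs,
         n_tp = nrow(pairs),
         n_fp = n_pred - nrow(pairs),
         n_fn = n_gt - nrow(pairs),
         n_gt = n_gt, n_pred = n_pred,
         iou_threshold = iou_threshold),
    class = "detection_match")
}

#' Object-detection precision, recall and F1
#'
#' precision = TP / (TP + FP), recall = TP / (TP + FN) and F1 their harmonic
#' mean. When a denominator is zero the corresponding metric is undefined
#' and reported as `NA` rather than silently as 0.
#'
#' @param match A `detection_match` from [match_objects()], or the true
#'   positive count (then `n_fp` and `n_fn` must be given).
#' @param n_fp,n_fn False positive / false negative counts when `match` is a
#'   plain count.
#' @return A one-row tibble with `n_tp`, `n_fp`, `n_fn`, `precision`,
#'   `recall`, `f1`.
#' @export
object_metrics <- function(match, n_fp = NULL, n_fn = NULL) {
  if (inherits(match, "detection_match")) {
    tp <- match$n_tp; fp <- match$n_fp; fn <- match$n_fn
  } else {
    tp <- match; fp <- n_fp; fn <- n_fn
  }
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tibble::tibble(n_tp = tp, n_fp = fp, n_fn = fn,
                 precision = precision, recall = recall,
                 f1 = f1_score(precision, recall))
}

#' F1 score from precision and recall
#'
#' @param precision,recall Fractions in [0, 1] (NA propagates).
#' @return The harmonic mean 2PR/(P+R); `NA` if either input is `NA` or both
#'   are zero.
#' @export
f1_score <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall) | (precision + recall) == 0,
         NA_real_, 2 * precision * recall / (precision + recall))
}

#' Pixel-level Matthews correlation coefficient
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)) over pixels.
#' If any factor of the denominator is zero the coefficient is defined as 0
#' (the usual convention for degenerate confusion tables).
#'
#' @param gt_mask,pred_mask Logical (or 0/1) matrices of the same shape.
#' @return MCC in [-1, 1].
#' @export
pixel_mcc <- function(gt_mask, pred_mask) {
  stopifnot(is.matrix(gt_mask), is.matrix(pred_mask))
  if (!identical(dim(gt_mask), dim(pred_mask))) {
    stop("`gt_mask` and `pred_mask` must share the same shape.", call. = FALSE)
  }
  g <- gt_mask != 0
  p <- pred_mask != 0
  tp <- sum(g & p); tn <- sum(!g & !p)
  fp <- sum(!g & p); fn <- sum(g & !p)
  mcc_from_counts(tp, tn, fp, fn)
}

# doubles avoid integer overflow on large pixel counts
mcc_from_counts <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' @export
print.detection_match <- function(x, ...) {
  cat(sprintf("<detection_match> IoU >= %.2f: TP %d, FP %d, FN %d (gt %d, pred %d)\n",
              x$iou_threshold, x$n_tp, x$n_fp, x$n_fn, x$n_gt, x$n_pred))
  invisible(x)
}
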