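#' Match detections to ground truth at an IoU threshold
#'
#' Greedy one-to-one matching, the convention of mainstream detection tooling:
#' detections are processed in descending confidence (ties broken by input
#' order, so results are reproducible); each detection claims the so-far
#' unmatched ground truth with the highest IoU provided that IoU reaches the
#' threshold, otherwise it is a false positive. Ground truths left unmatched
#' are false negatives. Matching is per image when an `image` column is
#' present, and assumes a single class per call (evaluate classes separately).
#'
#' @param dets box `data.frame` with confidences (and optionally `image`).
#' @param gts ground-truth box `data.frame` (same frame).
#' @param iou_threshold minimum IoU for a true positive (default 0.5).
#' @return A list of class `cb_matchset`: `order` (det row indices sorted by
#'   descending confidence), `is_tp` (logical, per sorted detection),
#'   `matched_gt` (gt row index or NA), `fn` (unmatched gt row indices),
#'   `n_gt`, `iou_threshold`.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  nd <- nrow(dets); ng <- nrow(gts)
  ord <- if (nd) order(-dets$confidence) else integer() # stable for ties
  is_tp <- logical(nd)
  matched_gt <- rep(NA_integer_, nd)
  gt_taken <- logical(ng)
  det_img <- if (!is.null(dets$image)) dets$image else rep("", nd)
  gt_img <- if (!is.null(gts$image)) gts$image else rep("", ng)
  if (nd && ng) {
    M <- iou_matrix(dets, gts)
    M[outer(det_img, gt_img, `!=`)] <- 0 # cross-image pairs never match
    for (k in seq_along(ord)) {
      i <- ord[k]
      cand <- which(!gt_taken & M[i, ] >= iou_threshold)
      if (length(cand)) {
        j <- cand[which.max(M[i, cand])]
        gt_taken[j] <- TRUE
        is_tp[k] <- TRUE
        matched_gt[k] <- j
      }
    }
  }
  structure(list(order = ord, is_tp = is_tp, matched_gt = matched_gt,
                 fn = which(!gt_taken), n_gt = ng,
                 iou_threshold = iou_threshold),
            class = "cb_matchset")
}

#' Precision-recall curve and operating point
#'
#' Cumulative precision and recall along the confidence-sorted detection list,
#' plus the scalar precision/recall at the all-detections operating point
#' (`precision = TP / (TP + FP)`, `recall = TP / n_gt`). With no ground truth
#' and no detections both scalars are defined as 1; with detections but no
#' ground truth, recall is flagged undefined (`NA`).
#'
#' @param match a `cb_matchset` from [match_detections()].
#' @param n_gt number of ground-truth boxes (defaults to the matchset's).
#' @return A list: `pr_points` (data.frame `recall`, `precision`, one row per
#'   detection in confidence order), `precision`, `recall`,
#'   `recall_undefined`.
#' @export
precision_recall <- function(match, n_gt = match$n_gt) {
  stopifnot(inherits(match, "cb_matchset"), n_gt >= 0)
  nd <- length(match$is_tp)
  if (nd == 0) {
    p <- if (n_gt == 0) 1 else 1 # no detections: vacuous precision 1
    r <- if (n_gt == 0) 1 else 0
    return(list(pr_points = data.frame(recall = numeric(),
                                       precision = numeric()),
                precision = p, recall = r, recall_undefined = FALSE))
  }
  tp_cum <- cumsum(match$is_tp)
  fp_cum <- cumsum(!match$is_tp)
  prec <- tp_cum / (tp_cum + fp_cum)
  rec <- if (n_gt > 0) tp_cum / n_gt else rep(NA_real_, nd)
  list(pr_points = data.frame(recall = rec, precision = prec),
       precision = prec[nd],
       recall = if (n_gt > 0) rec[nd] else NA_real_,
       recall_undefined = n_gt == 0)
}

#' Average precision at one IoU threshold
#'
#' All-point interpolation: the area under the precision envelope of the PR
#' staircase, `AP = sum over recall steps of (delta recall) x (max precision
#' at recall >= that step)`. Equals 1 for a perfect detection set and 0 when
#' there are ground truths but no detections.
#'
#' @inheritParams match_detections
#' @return AP in `[0, 1]` (`NA` when there is no ground truth).
#' @examples
#' gt <- boxes(0, c(.2, .7), c(.2, .7), .1, .1)
#' average_precision(transform(gt, confidence = 1), gt) # 1
#' @export
average_precision <- function(dets, gts, iou_threshold = 0.5) {
  if (nrow(gts) == 0) return(NA_real_)
  if (nrow(dets) == 0) return(0)
  m <- match_detections(dets, gts, iou_threshold)
  pr <- precision_recall(m)
  rec <- pr$pr_points$recall
  prec <- pr$pr_points$precision
  # precision envelope: max precision to the right of each point
  env <- rev(cummax(rev(prec)))
  drec <- diff(c(0, rec))
  sum(drec * env)
}

#' Mean average precision over classes and an IoU ladder
#'
#' AP is computed per class present in the ground truth and averaged across
#' classes at each threshold of the ladder (default 0.50 to 0.95 in steps of
#' 0.05); `map_overall` is the arithmetic mean over the ladder and `map50` the
#' value at threshold 0.5. With a single class the per-threshold mAP equals
#' that class's AP.
#'
#' @inheritParams match_detections
#' @param thresholds strictly increasing IoU ladder.
#' @return An object of class `cb_eval`: `ap_per_threshold` (named per-class
#'   matrix), `map_per_threshold`, `map50`, `map_overall`, `pr50` (the
#'   operating point and curve at the first threshold, per class).
#' @export
mean_ap <- function(dets, gts, thresholds = seq(50, 95, 5) / 100) {
  stopifnot(length(thresholds) >= 1, !is.unsorted(thresholds, strictly = TRUE))
  classes <- sort(unique(gts$class_id))
  if (!length(classes)) stop("no ground-truth boxes: mAP undefined")
  ap <- matrix(NA_real_, length(classes), length(thresholds),
               dimnames = list(paste0("class", classes),
                               sprintf("%.2f", thresholds)))
  pr50 <- list()
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    d <- dets[dets$class_id == cl, , drop = FALSE]
    g <- gts[gts$class_id == cl, , drop = FALSE]
    for (ti in seq_along(thresholds))
      ap[ci, ti] <- average_precision(d, g, thresholds[ti])
    m <- match_detections(d, g, thresholds[1])
    pr50[[paste0("class", cl)]] <- precision_recall(m)
  }
  map_thr <- colMeans(ap)
  structure(list(ap_per_threshold = ap,
                 map_per_threshold = map_thr,
                 map50 = unname(map_thr[1]),
                 map_overall = mean(map_thr),
                 thresholds = thresholds,
                 pr50 = pr50),
            class = "cb_eval")
}

#' @export
print.cb_eval <- function(x, ...) {
  cat(sprintf("<cb_eval mAP@%.2f=%.4f mAP[%.2f:%.2f]=%.4f>\n",
              x$thresholds[1], x$map50, min(x$thresholds), max(x$thresholds),
              x$map_overall))
  invisible(x)
}

#' Evaluate prediction files against ground-truth files
#'
#' Reads two YOLO label directories paired by basename and runs [mean_ap()].
#'
#' @param gt_dir,pred_dir directories of YOLO label files (predictions carry
#'   a sixth confidence field).
#' @param thresholds IoU ladder (default 0.5 only; use
#'   `seq(50, 95, 5) / 100` for the full ladder).
#' @return A `cb_eval`.
#' @export
evaluate_dirs <- function(gt_dir, pred_dir, thresholds = 0.5) {
  gts <- read_label_dir(gt_dir, has_confidence = FALSE)
  dets <- read_label_dir(pred_dir, has_confidence = TRUE)
  mean_ap(dets, gts, thresholds)
}
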