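#' Hard-negative mining configuration
#'
#' Controls how a detector's false positives are harvested as explicit
#' non-CB examples: the IoU threshold that defines a false positive, a global
#' cap on how many negatives may be kept relative to the number of CB ground
#' truths ("not more than the CB instances"), and a size band — negatives must
#' have width and height inside a percentile band of the ground-truth CB box
#' sizes ("shape similar to CBs").
#'
#' @param iou_threshold IoU at which a detection counts as matched (default
#'   0.5).
#' @param cap_ratio maximum mined negatives as a fraction of the CB
#'   ground-truth count, applied globally (default 1).
#' @param size_band length-2 probabilities: the percentile band of
#'   ground-truth widths/heights a negative must fall within (default 5th to
#'   95th).
#' @return A list of class `cb_mining_config`.
#' @export
mining_config <- function(iou_threshold = 0.5, cap_ratio = 1.0,
                          size_band = c(0.05, 0.95)) {
  stopifnot(iou_threshold > 0, iou_threshold < 1,
            cap_ratio > 0, cap_ratio <= 1,
            length(size_band) == 2, size_band[1] < size_band[2])
  structure(list(iou_threshold = iou_threshold, cap_ratio = cap_ratio,
                 size_band = size_band),
            class = "cb_mining_config")
}

#' Mine false positives as non-CB examples
#'
#' Detections that fail to match any CB ground truth at the configured IoU are
#' candidate negatives. They are filtered to the size band of the ground-truth
#' boxes, ranked by descending confidence (the most confident mistakes are the
#' hardest negatives), capped globally at `cap_ratio` times the total CB
#' ground-truth count, and relabelled class 1.
#'
#' @param dets detections with confidence (optionally with `image`).
#' @param gts class-0 ground truth in the same frame.
#' @param config a [mining_config()].
#' @return A box `data.frame` of class-1 negatives (confidence retained).
#' @export
mine_false_positives <- function(dets, gts, config = mining_config()) {
  stopifnot(inherits(config, "cb_mining_config"))
  gts_cb <- gts[gts$class_id == CB_CLASS, , drop = FALSE]
  if (nrow(dets) == 0) return(boxes(image = if (!is.null(dets$image)) character()))
  m <- match_detections(dets, gts_cb, config$iou_threshold)
  fp <- dets[m$order[!m$is_tp], , drop = FALSE]
  if (nrow(fp) && nrow(gts_cb)) {
    wb <- quantile(gts_cb$w, config$size_band, names = FALSE)
    hb <- quantile(gts_cb$h, config$size_band, names = FALSE)
    fp <- fp[fp$w >= wb[1] & fp$w <= wb[2] &
               fp$h >= hb[1] & fp$h <= hb[2], , drop = FALSE]
  }
  cap <- floor(config$cap_ratio * nrow(gts_cb))
  fp <- head(fp, cap) # already in descending confidence
  fp$class_id <- rep(NONCB_CLASS, nrow(fp))
  rownames(fp) <- NULL
  fp
}

#' Build the two-class dataset
#'
#' Merges mined class-1 negatives into the original class-0 label set. CB
#' boxes are never modified; a negative overlapping a CB ground truth at or
#' above the IoU threshold is dropped with a diagnostic, since it would
#' contradict its false-positive status.
#'
#' @param labels original ground-truth boxes (class 0).
#' @param negatives mined negatives (class 1), e.g. from
#'   [mine_false_positives()].
#' @param iou_threshold overlap at which a negative conflicts with a CB box.
#' @return A box `data.frame` containing the originals plus the surviving
#'   negatives.
#' @export
build_two_class_dataset <- function(labels, negatives, iou_threshold = 0.5) {
  stopifnot(all(negatives$class_id == NONCB_CLASS))
  if (nrow(negatives) == 0) return(labels)
  cb <- labels[labels$class_id == CB_CLASS, , drop = FALSE]
  keep <- rep(TRUE, nrow(negatives))
  if (nrow(cb)) {
    M <- iou_matrix(negatives, cb)
    neg_img <- if (!is.null(negatives$image)) negatives$image
      else rep("", nrow(negatives))
    cb_img <- if (!is.null(cb$image)) cb$image else rep("", nrow(cb))
    M[outer(neg_img, cb_img, `!=`)] <- 0
    conflict <- apply(M, 1, max) >= iou_threshold
    if (any(conflict))
      message(sum(conflict), " mined negative(s) dropped: IoU >= ",
              iou_threshold, " with a CB ground truth")
    keep <- !conflict
  }
  cols <- intersect(names(labels), names(negatives))
  neg <- negatives[keep, cols, drop = FALSE]
  # idempotence: a negative already present in the label set is not re-added
  key <- function(b) do.call(paste, c(b[intersect(c("image", "class_id", "cx",
                                                    "cy", "w", "h"), cols)],
                                      sep = "|"))
  neg <- neg[!key(neg) %in% key(labels), , drop = FALSE]
  out <- rbind(labels[, cols, drop = FALSE], neg)
  rownames(out) <- NULL
  out
}
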