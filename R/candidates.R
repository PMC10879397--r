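#' Candidate-centroblast criteria
#'
#' Centroblasts are large and approximately round; candidate cells are
#' retained when their equivalent circular diameter is at least
#' `min_equiv_diameter_um` and their rotated-rectangle aspect ratio falls in
#' `aspect_ratio_range`. Defaults are the operating values of the source
#' pipeline: 5.13 um minimum diameter, 0.7-1.3 ratio band, 0.12 um/px.
#'
#' @param min_equiv_diameter_um minimum equivalent diameter in microns.
#' @param aspect_ratio_range numeric length-2, acceptance band for the ratio.
#' @param um_per_px scan resolution in microns per pixel.
#' @return A list of class `cb_criteria`.
#' @export
candidate_criteria <- function(min_equiv_diameter_um = 5.13,
                               aspect_ratio_range = c(0.7, 1.3),
                               um_per_px = 0.12) {
  stopifnot(min_equiv_diameter_um > 0, length(aspect_ratio_range) == 2,
            aspect_ratio_range[1] < aspect_ratio_range[2], um_per_px > 0)
  structure(list(min_equiv_diameter_um = min_equiv_diameter_um,
                 aspect_ratio_range = aspect_ratio_range,
                 um_per_px = um_per_px),
            class = "cb_criteria")
}

#' Segment cells in a patch (classical stand-in)
#'
#' A pluggable segmentation front end: Otsu foreground (dark cells on light
#' background), morphological opening to suppress tiny noise, 8-connected
#' component labelling, and contour extraction. A deep-learning segmenter can
#' be substituted by supplying its label mask via `label_mask`, which follows
#' the same contract (integer matrix, 0 = background, one id per cell).
#'
#' @param p a `cb_patch`.
#' @param opening_radius disc radius in px for the noise-suppressing opening
#'   (default 2).
#' @param label_mask optional externally produced label matrix; when given the
#'   classical path is skipped.
#' @return A list of `cb_contour` (empty when Otsu is degenerate).
#' @export
segment_cells <- function(p, opening_radius = 2L, label_mask = NULL) {
  if (!is.null(label_mask)) {
    stopifnot(is.matrix(label_mask))
    return(contours_from_labels(label_mask))
  }
  stopifnot(inherits(p, "cb_patch"))
  ot <- otsu_binarize(patch_luminance(p))
  if (ot$degenerate) return(list())
  mask <- open_mask(ot$mask, opening_radius)
  contours_from_labels(label_components(mask), min_area = 2L)
}

#' Filter contours by the candidate-centroblast criteria
#'
#' @param contours list of `cb_contour`.
#' @param criteria a [candidate_criteria()].
#' @return A list with `kept` (the passing contours) and `verdicts`, a
#'   data.frame with per-contour diameter, ratio, pass flags and the failure
#'   reason (`"ok"`, `"diameter"`, `"aspect_ratio"`, or
#'   `"diameter+aspect_ratio"`).
#' @export
filter_candidates <- function(contours, criteria = candidate_criteria()) {
  stopifnot(inherits(criteria, "cb_criteria"))
  n <- length(contours)
  d <- vapply(contours, function(ct)
    equivalent_diameter_um(ct$area_px2, criteria$um_per_px), 1.0)
  r <- vapply(contours, aspect_ratio, 1.0)
  pass_d <- d >= criteria$min_equiv_diameter_um
  pass_r <- r >= criteria$aspect_ratio_range[1] &
    r <= criteria$aspect_ratio_range[2]
  reason <- rep("ok", n)
  reason[!pass_d & pass_r] <- "diameter"
  reason[pass_d & !pass_r] <- "aspect_ratio"
  reason[!pass_d & !pass_r] <- "diameter+aspect_ratio"
  verdicts <- data.frame(contour = seq_len(n), equiv_diameter_um = d,
                         aspect_ratio = r, pass_diameter = pass_d,
                         pass_aspect = pass_r, kept = pass_d & pass_r,
                         reason = reason)
  list(kept = contours[verdicts$kept], verdicts = verdicts)
}

#' Built-in baseline detector
#'
#' Runs the classical segmentation stand-in, applies the candidate filter, and
#' emits one normalized axis-aligned box per kept contour. Confidence is a
#' monotone function of the equivalent diameter,
#' `clamp(d_um / (2 * min_equiv_diameter_um), 0, 1)`, so a contour exactly at
#' the diameter threshold scores 0.5. This lets the full pipeline run without
#' trained detector weights; predictions from a real model are supplied as
#' YOLO files instead.
#'
#' @param p a `cb_patch`.
#' @param criteria a [candidate_criteria()].
#' @param opening_radius forwarded to [segment_cells()].
#' @return A box `data.frame` with confidences, class 0.
#' @export
baseline_detect <- function(p, criteria = candidate_criteria(),
                            opening_radius = 2L) {
  cts <- segment_cells(p, opening_radius = opening_radius)
  fc <- filter_candidates(cts, criteria)
  kept <- fc$kept
  if (!length(kept)) return(boxes())
  H <- dim(p$pixels)[1]; W <- dim(p$pixels)[2]
  d <- fc$verdicts$equiv_diameter_um[fc$verdicts$kept]
  bb <- t(vapply(kept, function(ct) ct$bbox, c(xmin = 0, ymin = 0,
                                               xmax = 0, ymax = 0)))
  boxes(CB_CLASS,
        cx = (bb[, "xmin"] + bb[, "xmax"] + 1) / 2 / W,
        cy = (bb[, "ymin"] + bb[, "ymax"] + 1) / 2 / H,
        w = (bb[, "xmax"] - bb[, "xmin"] + 1) / W,
        h = (bb[, "ymax"] - bb[, "ymin"] + 1) / H,
        confidence = pmin(pmax(d / (2 * criteria$min_equiv_diameter_um), 0), 1))
}
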