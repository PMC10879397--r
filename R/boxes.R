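#' Bounding-box containers
#'
#' Boxes follow the YOLO convention: class id plus center (`cx`, `cy`) and
#' size (`w`, `h`), all normalized to the image dimensions, with an optional
#' detection `confidence` (NA for ground truth). A box set is a plain
#' `data.frame` so the usual subsetting and binding idioms apply; an optional
#' `image` column associates boxes with an image identifier in multi-image
#' sets.
#'
#' @param class_id integer class ids (0 = CB, 1 = non-CB).
#' @param cx,cy normalized box centers in `[0, 1]`.
#' @param w,h normalized box sizes in `(0, 1]`.
#' @param confidence optional detection confidences in `[0, 1]`; `NA` marks
#'   ground truth.
#' @param image optional image identifiers.
#' @return A `data.frame` with columns `class_id, cx, cy, w, h, confidence`
#'   (and `image` when supplied).
#' @examples
#' boxes(0, cx = 0.5, cy = 0.5, w = 0.1, h = 0.2)
#' @export
boxes <- function(class_id = integer(), cx = numeric(), cy = numeric(),
                  w = numeric(), h = numeric(), confidence = NA_real_,
                  image = NULL) {
  n <- max(length(cx), length(cy), length(w), length(h),
           if (length(class_id) > 1) length(class_id) else 0L)
  out <- data.frame(class_id = as.integer(rep_len(class_id, n)),
                    cx = as.numeric(rep_len(cx, n)),
                    cy = as.numeric(rep_len(cy, n)),
                    w = as.numeric(rep_len(w, n)),
                    h = as.numeric(rep_len(h, n)),
                    confidence = as.numeric(rep_len(confidence, n)))
  if (!is.null(image)) out$image <- rep_len(image, n)
  validate_boxes(out)
  out
}

#' @rdname boxes
#' @param x a candidate box `data.frame`.
#' @export
validate_boxes <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("class_id", "cx", "cy", "w", "h") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  bad <- x$cx < 0 | x$cx > 1 | x$cy < 0 | x$cy > 1 |
    x$w <= 0 | x$w > 1 | x$h <= 0 | x$h > 1
  if (any(bad))
    stop("invalid box(es) at row(s): ", paste(which(bad), collapse = ", "))
  if ("confidence" %in% names(x)) {
    cf <- x$confidence
    if (any(!is.na(cf) & (cf < 0 | cf > 1)))
      stop("confidence out of [0, 1]")
  }
  invisible(x)
}

# corner representation (x0, y0, x1, y1), half-open, in the normalized frame
box_corners <- function(b) {
  cbind(x0 = b$cx - b$w / 2, y0 = b$cy - b$h / 2,
        x1 = b$cx + b$w / 2, y1 = b$cy + b$h / 2)
}

#' Intersection over union of two boxes
#'
#' Overlap ratio between two axis-aligned boxes in the same coordinate frame:
#' intersection area divided by union area. Disjoint boxes score 0; identical
#' boxes score 1. A zero-area box yields 0 with a warning.
#'
#' @param a,b single-row box data frames (see [boxes()]), or numeric vectors
#'   `c(cx, cy, w, h)`.
#' @return IoU in `[0, 1]`.
#' @examples
#' iou(c(0.5, 0.5, 0.2, 0.2), c(0.5, 0.5, 0.2, 0.2)) # 1
#' @export
iou <- function(a, b) {
  if (is.numeric(a)) a <- boxes(0L, a[1], a[2], a[3], a[4])
  if (is.numeric(b)) b <- boxes(0L, b[1], b[2], b[3], b[4])
  iou_matrix(a, b)[1, 1]
}

# pairwise IoU: rows = boxes in a, cols = boxes in b
iou_matrix <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0)
    return(matrix(numeric(0), nrow(a), nrow(b)))
  ca <- box_corners(a); cb <- box_corners(b)
  areas_a <- a$w * a$h
  areas_b <- b$w * b$h
  if (any(areas_a <= 0) || any(areas_b <= 0))
    warning("zero-area box; IoU reported as 0")
  ix0 <- outer(ca[, "x0"], cb[, "x0"], pmax)
  iy0 <- outer(ca[, "y0"], cb[, "y0"], pmax)
  ix1 <- outer(ca[, "x1"], cb[, "x1"], pmin)
  iy1 <- outer(ca[, "y1"], cb[, "y1"], pmin)
  inter <- pmax(ix1 - ix0, 0) * pmax(iy1 - iy0, 0)
  un <- outer(areas_a, areas_b, `+`) - inter
  out <- ifelse(un > 0, inter / un, 0)
  matrix(out, nrow(a), nrow(b))
}
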