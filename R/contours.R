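#' Cell contours from a label image
#'
#' Converts a labelled mask (integer matrix, 0 = background) into a list of
#' `cb_contour` objects. Each records its pixel area, axis-aligned bounding
#' box, the convex-hull polygon of its pixels (0-based x/y, pixel centers),
#' and the side lengths of the minimum-area rotated bounding rectangle fitted
#' to that hull. Components touching the image border are kept.
#'
#' @param lab integer label matrix, e.g. from [label_components()].
#' @param min_area drop components smaller than this many pixels (default 1).
#' @return A list of `cb_contour`, ordered by label.
#' @export
contours_from_labels <- function(lab, min_area = 1L) {
  st <- component_stats(lab)
  st <- st[st$area >= min_area, , drop = FALSE]
  out <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    sel <- which(lab == st$label[i], arr.ind = TRUE)
    # 0-based pixel coordinates: x = col - 1, y = row - 1
    pts <- cbind(x = sel[, 2] - 1, y = sel[, 1] - 1)
    hull <- pts[grDevices::chull(pts), , drop = FALSE]
    axes <- min_area_rect_axes(pts)
    out[[i]] <- structure(list(polygon = hull,
                               area_px2 = st$area[i],
                               axis_lengths = axes,
                               bbox = c(xmin = st$xmin[i] - 1L,
                                        ymin = st$ymin[i] - 1L,
                                        xmax = st$xmax[i] - 1L,
                                        ymax = st$ymax[i] - 1L)),
                          class = "cb_contour")
  }
  out
}

#' @export
print.cb_contour <- function(x, ...) {
  cat(sprintf("<cb_contour area=%g px2 axes=%.1fx%.1f px>\n",
              x$area_px2, x$axis_lengths[1], x$axis_lengths[2]))
  invisible(x)
}

# Minimum-area rotated bounding rectangle via rotating calipers on the convex
# hull: one side of the optimal rectangle is collinear with a hull edge.
# Returns side lengths (a, b) in fitted order (a = along the edge), each
# padded by 1 px so a w x h axis-aligned block of pixel centers measures w x h.
min_area_rect_axes <- function(pts) {
  pts <- unique(pts[, 1:2, drop = FALSE])
  n <- nrow(pts)
  if (n == 0) stop("degenerate contour: no pixels")
  if (n == 1) return(c(1, 1))
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  m <- nrow(hull)
  if (m < 2) return(c(1, 1))
  best <- NULL; best_area <- Inf
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len; v <- c(-u[2], u[1])
    pu <- hull %*% u; pv <- hull %*% v
    a <- diff(range(pu)) + 1 # pixel centers -> extent in pixel units
    b <- diff(range(pv)) + 1
    if (a * b < best_area) {
      best_area <- a * b
      best <- c(a, b)
    }
  }
  if (is.null(best)) c(1, 1) else as.numeric(best)
}

#' Equivalent circular diameter in microns
#'
#' The diameter of the circle that would have the same area as the contour,
#' converted from pixels to microns by the scan resolution:
#' `2 * sqrt(area / pi) * um_per_px`. Used as the size criterion for candidate
#' centroblasts (cells tend to be large: threshold 5.13 um at 0.12 um/px).
#'
#' @param area_px2 contour area in squared pixels (>= 0).
#' @param um_per_px microns per pixel (default 0.12).
#' @return Diameter in microns; vectorized.
#' @examples
#' equivalent_diameter_um(pi * 50^2) # 12 um at the default resolution
#' @export
equivalent_diameter_um <- function(area_px2, um_per_px = 0.12) {
  if (any(area_px2 < 0)) stop("area must be non-negative")
  stopifnot(um_per_px > 0)
  2 * sqrt(area_px2 / pi) * um_per_px
}

#' Aspect ratio of a contour
#'
#' Ratio of the fitted rotated bounding rectangle's first side to its second
#' side, in fitted order (not sorted), so values both below and above 1 occur
#' and the symmetric acceptance band 0.7-1.3 treats elongation in either
#' direction alike.
#'
#' @param contour a `cb_contour`.
#' @return The ratio a / b.
#' @export
aspect_ratio <- function(contour) {
  ax <- contour$axis_lengths
  if (any(ax <= 0)) stop("degenerate contour: zero-length axis")
  ax[1] / ax[2]
}
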