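#' Background-removal configuration
#'
#' @param dilate_radius disc radius in px for the mask dilation step
#'   (default 2; the source procedure names the operation but not the kernel).
#' @param fill_ratio contours with area below this fraction of the average
#'   bounding-rectangle area get their interiors filled solid (default 0.5,
#'   i.e. "less than half of the average area").
#' @param degenerate_policy what to do when Otsu is undefined (single-valued
#'   histogram): `"passthrough"` returns the input unchanged (the default for
#'   [remove_background()]), `"empty"` treats everything as background.
#' @return A list of class `cb_preprocess_config`.
#' @export
preprocess_config <- function(dilate_radius = 2L, fill_ratio = 0.5,
                              degenerate_policy = c("passthrough", "empty")) {
  stopifnot(dilate_radius >= 1, fill_ratio > 0, fill_ratio < 1)
  structure(list(dilate_radius = as.integer(dilate_radius),
                 fill_ratio = fill_ratio,
                 degenerate_policy = match.arg(degenerate_policy)),
            class = "cb_preprocess_config")
}

#' Histogram equalization on luminance
#'
#' Equalizes the 8-bit luminance channel with the standard cumulative-histogram
#' mapping `round((cdf(v) - cdf_min) / (N - cdf_min) * 255)` and rescales the
#' RGB channels multiplicatively so chromaticity is preserved (no hue shift,
#' which matters for stain-color semantics). The intensity mapping is monotone
#' non-decreasing; a constant-luminance patch is returned unchanged.
#'
#' @param p a `cb_patch`.
#' @return An equalized `cb_patch` with the same provenance fields.
#' @export
equalize_histogram <- function(p) {
  stopifnot(inherits(p, "cb_patch"))
  y <- patch_luminance(p)
  h <- tabulate(as.vector(y) + 1L, 256L)
  if (sum(h > 0) <= 1) return(p) # degenerate histogram: identity
  cdf <- cumsum(h)
  cdf_min <- min(cdf[cdf > 0])
  n <- length(y)
  lut <- as.integer(round((cdf - cdf_min) / (n - cdf_min) * 255))
  lut <- pmin(pmax(lut, 0L), 255L)
  y_new <- matrix(lut[as.vector(y) + 1L], nrow(y), ncol(y))
  scale <- ifelse(y > 0, y_new / pmax(y, 1L), 0)
  px <- p$pixels
  out <- array(0L, dim(px))
  for (ch in 1:3) {
    v <- px[, , ch] * scale
    v[y == 0] <- y_new[y == 0] # black pixels have no chroma to preserve
    out[, , ch] <- as.integer(round(pmin(pmax(v, 0), 255)))
  }
  patch(out, origin_xy = p$origin_xy, um_per_px = p$um_per_px)
}

#' Otsu's global threshold
#'
#' Picks the 8-bit threshold `t` maximizing the between-class variance of the
#' two classes `[0, t]` and `[t+1, 255]`; ties resolve to the smallest such
#' `t`. Because cells are dark on a light background throughout this pipeline,
#' the foreground mask marks pixels `<= t`.
#'
#' @param gray integer matrix of 8-bit gray values (0-255), e.g. from the
#'   luminance of a patch.
#' @param degenerate_policy `"empty"` (default): a single-valued histogram
#'   yields an all-`FALSE` mask and `NA` threshold; `"passthrough"` is mapped
#'   to the same mask here (callers decide what to do with the flag).
#' @return A list `(mask = logical matrix, threshold = integer or NA)`.
#' @export
otsu_binarize <- function(gray, degenerate_policy = "empty") {
  stopifnot(is.matrix(gray), all(gray >= 0), all(gray <= 255))
  gray <- matrix(as.integer(round(gray)), nrow(gray), ncol(gray))
  h <- tabulate(as.vector(gray) + 1L, 256L)
  if (sum(h > 0) <= 1)
    return(list(mask = matrix(FALSE, nrow(gray), ncol(gray)),
                threshold = NA_integer_, degenerate = TRUE))
  n <- sum(h)
  levels <- 0:255
  w0 <- cumsum(h) / n                 # class [0, t]
  sum0 <- cumsum(h * levels)
  mu_t <- sum0[256] / n
  mu0 <- ifelse(w0 > 0, sum0 / (n * w0), 0)
  w1 <- 1 - w0
  mu1 <- ifelse(w1 > 0, (mu_t - w0 * mu0) / w1, 0)
  sigma_b <- w0 * w1 * (mu0 - mu1)^2  # between-class variance at each t
  sigma_b[256] <- -Inf                # t = 255 puts everything in one class
  t <- which.max(sigma_b) - 1L        # smallest argmax
  list(mask = gray <= t, threshold = t, degenerate = FALSE)
}

#' Remove non-cell background from a patch
#'
#' The background-removal procedure: (1) histogram-equalize; (2) convert to
#' grayscale; (3) Otsu-threshold into a dark-foreground mask; (4) detect
#' contours (8-connected components); (5) compute the average area of their
#' axis-aligned bounding rectangles; (6) dilate the mask; (7) for each contour
#' whose area is below `fill_ratio` of that average, fill its interior solid;
#' (8) use the mask to keep foreground pixels of the ORIGINAL patch and paint
#' every unselected pixel white (255,255,255). When Otsu is degenerate the
#' input is returned unchanged with a message.
#'
#' @param p a `cb_patch`.
#' @param config a [preprocess_config()].
#' @param mode `"algorithm"` (default) runs the contour pipeline above;
#'   `"mean_white"` is an alternative simple mode that whitens every pixel
#'   whose luminance exceeds the patch's mean luminance.
#' @return A `cb_patch` in which every pixel is either its original value or
#'   pure white.
#' @export
remove_background <- function(p, config = preprocess_config(),
                              mode = c("algorithm", "mean_white")) {
  stopifnot(inherits(p, "cb_patch"))
  mode <- match.arg(mode)
  if (mode == "mean_white") {
    y <- patch_luminance(p)
    keep <- y <= mean(y)
    return(apply_mask_white(p, keep))
  }
  eq <- equalize_histogram(p)
  gray <- patch_luminance(eq)
  ot <- otsu_binarize(gray)
  if (ot$degenerate) {
    if (config$degenerate_policy == "passthrough") {
      message("degenerate Otsu histogram: returning patch unchanged")
      return(p)
    }
    return(apply_mask_white(p, matrix(FALSE, nrow(gray), ncol(gray))))
  }
  lab <- label_components(ot$mask)
  stats <- component_stats(lab)
  avg_rect_area <- if (nrow(stats)) mean(stats$rect_area) else 0
  mask <- dilate_mask(ot$mask, config$dilate_radius)
  small <- stats$label[stats$area < config$fill_ratio * avg_rect_area]
  if (length(small)) {
    small_mask <- matrix(lab %in% small, nrow(lab), ncol(lab))
    # solidify small contours: fill enclosed holes of those regions only
    filled <- fill_holes(small_mask)
    mask <- mask | filled
  }
  apply_mask_white(p, mask)
}

# keep pixels where mask is TRUE; set the rest to white
apply_mask_white <- function(p, mask) {
  px <- p$pixels
  out <- px
  for (ch in 1:3) {
    v <- out[, , ch]
    v[!mask] <- 255L
    out[, , ch] <- v
  }
  patch(out, origin_xy = p$origin_xy, um_per_px = p$um_per_px)
}

# per-component pixel area and axis-aligned bounding-rectangle geometry
component_stats <- function(lab) {
  labs <- sort(unique(lab[lab > 0]))
  if (!length(labs))
    return(data.frame(label = integer(), area = numeric(),
                      rect_area = numeric(), xmin = integer(),
                      xmax = integer(), ymin = integer(), ymax = integer()))
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  ymin <- tapply(idx[, 1], l, min); ymax <- tapply(idx[, 1], l, max)
  xmin <- tapply(idx[, 2], l, min); xmax <- tapply(idx[, 2], l, max)
  area <- tapply(l, l, length)
  ord <- as.character(labs)
  data.frame(label = labs,
             area = as.numeric(area[ord]),
             rect_area = as.numeric((xmax[ord] - xmin[ord] + 1) *
                                      (ymax[ord] - ymin[ord] + 1)),
             xmin = as.integer(xmin[ord]), xmax = as.integer(xmax[ord]),
             ymin = as.integer(ymin[ord]), ymax = as.integer(ymax[ord]))
}
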