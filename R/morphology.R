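#' Binary mask primitives
#'
#' Thin wrappers over the package's compiled raster kernels: connected-component
#' labelling (8-connected foreground by default), disc-shaped dilation/erosion,
#' morphological opening, and hole filling (4-connected background regions not
#' reachable from the border become foreground).
#'
#' @param mask logical matrix (rows = y, cols = x).
#' @param connectivity 4 or 8.
#' @return `label_components()` an integer matrix of labels (0 = background);
#'   the others a logical matrix.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  .label_components_cpp(mask, as.integer(connectivity))
}

#' @rdname label_components
#' @param radius disc radius in pixels.
#' @export
dilate_mask <- function(mask, radius = 2L) .dilate_cpp(mask, as.integer(radius))

#' @rdname label_components
#' @export
erode_mask <- function(mask, radius = 2L) .erode_cpp(mask, as.integer(radius))

#' @rdname label_components
#' @export
open_mask <- function(mask, radius = 2L)
  .dilate_cpp(.erode_cpp(mask, as.integer(radius)), as.integer(radius))

#' @rdname label_components
#' @export
fill_holes <- function(mask) .fill_holes_cpp(mask)
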