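#' Patch: an RGB raster with provenance
#'
#' A patch is an 8-bit RGB raster (stored as an integer `H x W x 3` array,
#' values 0-255) together with the pixel offset of its top-left corner in the
#' source image (0-based) and the scan resolution in microns per pixel. The
#' default resolution, 0.12 um/px, is that of a 40x scan on the scanner the
#' training slides came from; every physical-size computation in the package
#' flows through this value.
#'
#' @param pixels numeric or integer `H x W x 3` array; values either 0-255 or
#'   0-1 (auto-rescaled).
#' @param origin_xy integer length-2 vector, pixel offset `(x, y)` of the
#'   top-left corner in the source image.
#' @param um_per_px microns per pixel (> 0).
#' @return An object of class `cb_patch`.
#' @export
patch <- function(pixels, origin_xy = c(0L, 0L), um_per_px = 0.12) {
  if (length(dim(pixels)) == 2) # grayscale in: replicate to RGB
    pixels <- array(rep(pixels, 3), c(dim(pixels), 3))
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            dim(pixels)[1] > 0, dim(pixels)[2] > 0,
            um_per_px > 0, all(origin_xy >= 0))
  if (max(pixels) <= 1 && !is.integer(pixels))
    pixels <- pixels * 255
  pixels <- array(as.integer(round(pmin(pmax(pixels, 0), 255))), dim(pixels))
  structure(list(pixels = pixels,
                 origin_xy = as.integer(origin_xy),
                 um_per_px = as.numeric(um_per_px)),
            class = "cb_patch")
}

#' @export
print.cb_patch <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<cb_patch %dx%d px at (%d,%d), %.3f um/px>\n",
              d[2], d[1], x$origin_xy[1], x$origin_xy[2], x$um_per_px))
  invisible(x)
}

#' @export
dim.cb_patch <- function(x) dim(x$pixels)

#' Cut an image into non-overlapping square tiles
#'
#' Tiles are laid on a regular grid from the image origin with stride equal to
#' `tile_size`; partial tiles at the right/bottom edges are dropped, not
#' padded, so every emitted tile is exactly `tile_size` squared. An image
#' smaller than `tile_size` in either dimension yields an empty list.
#'
#' @param image an RGB array, matrix, or `cb_patch`.
#' @param tile_size tile side length in pixels (>= 32); the pipeline default
#'   is 512.
#' @param um_per_px resolution forwarded to each tile (taken from the patch
#'   when `image` is a `cb_patch`).
#' @return A list of `cb_patch`, each recording its origin offset, in
#'   column-major grid order (left-to-right, then top-to-bottom).
#' @examples
#' img <- array(128L, c(1024, 1024, 3))
#' length(tile_image(img, 512)) # 4
#' @export
tile_image <- function(image, tile_size = 512L, um_per_px = 0.12) {
  if (inherits(image, "cb_patch")) {
    um_per_px <- image$um_per_px
    image <- image$pixels
  }
  stopifnot(tile_size >= 32)
  if (length(dim(image)) == 2)
    image <- array(rep(image, 3), c(dim(image), 3))
  H <- dim(image)[1]; W <- dim(image)[2]
  ny <- H %/% tile_size; nx <- W %/% tile_size
  out <- vector("list", nx * ny)
  k <- 0
  for (ty in seq_len(ny)) {
    for (tx in seq_len(nx)) {
      y0 <- (ty - 1L) * tile_size; x0 <- (tx - 1L) * tile_size
      k <- k + 1
      out[[k]] <- patch(image[(y0 + 1):(y0 + tile_size),
                              (x0 + 1):(x0 + tile_size), , drop = FALSE],
                        origin_xy = c(x0, y0), um_per_px = um_per_px)
    }
  }
  out
}

#' Read and write patches as PNG
#'
#' @param path PNG file path.
#' @param um_per_px resolution to record on the patch.
#' @return `read_patch()` returns a `cb_patch`; `write_patch()` returns the
#'   path invisibly.
#' @export
read_patch <- function(path, um_per_px = 0.12) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3 && dim(px)[3] == 4)
    px <- px[, , 1:3, drop = FALSE] # drop alpha
  patch(px, um_per_px = um_per_px)
}

#' @rdname read_patch
#' @param p a `cb_patch`.
#' @export
write_patch <- function(p, path) {
  stopifnot(inherits(p, "cb_patch"))
  png::writePNG(p$pixels / 255, path)
  invisible(path)
}

# 8-bit luminance (Rec. 601 weights), rounded to integers 0..255
patch_luminance <- function(p) {
  px <- if (inherits(p, "cb_patch")) p$pixels else p
  y <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  matrix(as.integer(round(pmin(pmax(y, 0), 255))), dim(px)[1], dim(px)[2])
}
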