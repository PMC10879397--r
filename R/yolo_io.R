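#' Read annotations in the YOLO text dialect
#'
#' Each non-blank line is `"class cx cy w h [conf]"` with whitespace
#' separators and normalized coordinates. Lines with out-of-range coordinates
#' or non-positive sizes are rejected with a warning naming the line number;
#' valid lines are kept in input order.
#'
#' @param con a file path, connection, or character vector of lines.
#' @param has_confidence if `TRUE`, a sixth confidence field is expected
#'   (prediction files); if `NA` (default) it is auto-detected per line.
#' @return A box `data.frame` (see [boxes()]).
#' @examples
#' read_yolo_labels("0 0.5 0.5 0.1 0.2")
#' @export
read_yolo_labels <- function(con, has_confidence = NA) {
  lines <- if (is.character(con) && length(con) == 1 && file.exists(con))
    readLines(con, warn = FALSE) else if (inherits(con, "connection"))
      readLines(con, warn = FALSE) else as.character(con)
  out <- boxes()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    f <- suppressWarnings(as.numeric(strsplit(ln, "[[:space:]]+")[[1]]))
    nf <- length(f)
    expect_conf <- if (is.na(has_confidence)) nf == 6 else isTRUE(has_confidence)
    ok <- !anyNA(f) && nf == (5L + as.integer(expect_conf)) &&
      f[1] >= 0 && f[1] == floor(f[1]) &&
      f[2] >= 0 && f[2] <= 1 && f[3] >= 0 && f[3] <= 1 &&
      f[4] > 0 && f[4] <= 1 && f[5] > 0 && f[5] <= 1 &&
      (!expect_conf || (f[6] >= 0 && f[6] <= 1))
    if (!ok) {
      warning("rejecting malformed label at line ", i, ": '", ln, "'",
              call. = FALSE)
      next
    }
    out <- rbind(out, data.frame(class_id = as.integer(f[1]), cx = f[2],
                                 cy = f[3], w = f[4], h = f[5],
                                 confidence = if (expect_conf) f[6] else NA_real_))
  }
  out
}

#' Write annotations in the YOLO text dialect
#'
#' One line per box, fields formatted to six decimals; the confidence field is
#' emitted only for boxes where it is not `NA`. Deterministic: the output is a
#' pure function of the box set, and `read_yolo_labels(write_yolo_labels(b))`
#' recovers `b` up to the 6-decimal quantization.
#'
#' @param b a box `data.frame`.
#' @param path optional file path; when `NULL` the text is returned invisibly
#'   as a character vector of lines.
#' @return The lines, invisibly.
#' @export
write_yolo_labels <- function(b, path = NULL) {
  validate_boxes(b)
  fmt <- function(x) sprintf("%.6f", x)
  lines <- character(nrow(b))
  for (i in seq_len(nrow(b))) {
    base <- paste(b$class_id[i], fmt(b$cx[i]), fmt(b$cy[i]),
                  fmt(b$w[i]), fmt(b$h[i]))
    cf <- if ("confidence" %in% names(b)) b$confidence[i] else NA_real_
    lines[i] <- if (is.na(cf)) base else paste(base, fmt(cf))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a directory of YOLO label files
#'
#' Files are paired to images by shared basename (the de-facto YOLO layout:
#' `images/x.png` pairs with `labels/x.txt`). Returns one box `data.frame`
#' with an `image` column holding the basename without extension.
#'
#' @param dir directory containing `.txt` label files.
#' @param has_confidence passed to [read_yolo_labels()].
#' @return A box `data.frame` with an `image` column (empty if no files).
#' @export
read_label_dir <- function(dir, has_confidence = NA) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  out <- lapply(files, function(f) {
    b <- read_yolo_labels(f, has_confidence)
    if (nrow(b)) b$image <- tools::file_path_sans_ext(basename(f))
    b
  })
  out <- out[vapply(out, nrow, 1L) > 0]
  if (!length(out)) return(boxes(image = character()))
  do.call(rbind, out)
}

#' Write per-image YOLO label files
#'
#' @param b a box `data.frame` with an `image` column.
#' @param dir output directory (created if needed).
#' @param images optional character vector of image ids that must get a file
#'   even when they have no boxes (empty files).
#' @return The directory, invisibly.
#' @export
write_label_dir <- function(b, dir, images = NULL) {
  stopifnot("image" %in% names(b) || nrow(b) == 0)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- unique(c(if (nrow(b)) unique(b$image), images))
  for (id in ids) {
    sub <- if (nrow(b)) b[b$image == id, , drop = FALSE] else b
    write_yolo_labels(sub, file.path(dir, paste0(id, ".txt")))
  }
  invisible(dir)
}
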