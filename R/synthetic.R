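#' Scene specification for synthetic H&E-like patches
#'
#' Describes a patch to render: a textured light background in one of two
#' stain palettes — `"purple"` for fresh hematoxylin-rich slides, `"pink"` for
#' aged slides whose hematoxylin has faded leaving eosin — populated with
#' filled elliptical cells. CB-like cells are large and round (default
#' diameters 7-10 um, within-cell axis ratio up to 1.25); clutter cells are
#' either small round cells (2.5-4.5 um) or large elongated ones (axis ratio
#' 2-3), both of which the candidate filter must reject. Rendering is a pure
#' function of the spec, including its seed.
#'
#' @param n_cb number of CB-like cells.
#' @param n_other number of clutter cells.
#' @param stain_mode `"purple"` or `"pink"`.
#' @param size_px patch side length in pixels (default 512).
#' @param um_per_px resolution (default 0.12).
#' @param cb_diameter_um CB equivalent-diameter range in microns.
#' @param other_diameter_um clutter (small round) diameter range.
#' @param elong_diameter_um elongated-clutter equivalent-diameter range.
#' @param elong_aspect elongated-clutter axis-ratio range.
#' @param noise_sd additive Gaussian pixel noise, 8-bit levels (default 3).
#' @param texture_amp amplitude of the low-frequency multiplicative
#'   background field (default 0.04), which keeps the background from being
#'   trivially uniform for Otsu.
#' @param overlap_allowed may cells overlap (default `FALSE`).
#' @param seed integer seed; identical specs render byte-identical patches.
#' @return A list of class `cb_scene_spec`.
#' @export
scene_spec <- function(n_cb = 5L, n_other = 5L,
                       stain_mode = c("purple", "pink"),
                       size_px = 512L, um_per_px = 0.12,
                       cb_diameter_um = c(7, 10),
                       other_diameter_um = c(2.5, 4.5),
                       elong_diameter_um = c(6, 9),
                       elong_aspect = c(2, 3),
                       noise_sd = 3, texture_amp = 0.04,
                       overlap_allowed = FALSE, seed = 1L) {
  stopifnot(n_cb >= 0, n_other >= 0, size_px >= 64, um_per_px > 0,
            all(cb_diameter_um > 0), all(other_diameter_um > 0),
            noise_sd >= 0, texture_amp >= 0)
  structure(list(n_cb = as.integer(n_cb), n_other = as.integer(n_other),
                 stain_mode = match.arg(stain_mode),
                 size_px = as.integer(size_px), um_per_px = um_per_px,
                 cb_diameter_um = cb_diameter_um,
                 other_diameter_um = other_diameter_um,
                 elong_diameter_um = elong_diameter_um,
                 elong_aspect = elong_aspect,
                 noise_sd = noise_sd, texture_amp = texture_amp,
                 overlap_allowed = isTRUE(overlap_allowed),
                 seed = as.integer(seed)),
            class = "cb_scene_spec")
}

# palette anchors (RGB 0-255): cell vs background per stain mode; chosen so
# cell/background luminance contrast comfortably exceeds 60 levels
stain_palette <- function(mode) {
  if (mode == "purple")
    list(bg = c(231, 218, 236), cell = c(118, 62, 150))
  else
    list(bg = c(247, 228, 233), cell = c(205, 110, 140))
}

#' Render a synthetic patch with ground-truth boxes
#'
#' Cells are rasterized as filled rotated ellipses over a textured light
#' background; each CB's class-0 box is the exact axis-aligned bounding box of
#' its rasterized pixel set, normalized to the image size. With
#' `overlap_allowed = FALSE` cell placements are rejected-sampled to keep
#' every pair of cells disjoint with a safety margin; if no placement is found
#' after bounded retries an error is raised.
#'
#' @param spec a [scene_spec()].
#' @return A list: `patch` (a `cb_patch`), `gt` (class-0 boxes for the CBs),
#'   `cells` (data.frame of true per-cell geometry: population, center, axes
#'   in px, rotation, true equivalent diameter in um and axis ratio).
#' @export
generate_patch <- function(spec) {
  stopifnot(inherits(spec, "cb_scene_spec"))
  with_seed(spec$seed, {
    S <- spec$size_px
    pal <- stain_palette(spec$stain_mode)
    # background: palette anchor times a smooth multiplicative field
    field <- smooth_field(S, amp = spec$texture_amp)
    px <- array(0, c(S, S, 3))
    for (ch in 1:3) px[, , ch] <- pal$bg[ch] * field

    cells <- plan_cells(spec)
    xs <- matrix(rep(0:(S - 1), each = S), S, S)  # x per pixel (col index)
    ys <- matrix(rep(0:(S - 1), times = S), S, S) # y per pixel (row index)
    gt <- boxes()
    if (nrow(cells)) {
      for (i in seq_len(nrow(cells))) {
        cc <- cells[i, ]
        shade <- runif(1, 0.85, 1.1)
        col <- pmin(pal$cell * shade, 255)
        dx <- xs - cc$cx_px; dy <- ys - cc$cy_px
        u <- (dx * cos(cc$theta) + dy * sin(cc$theta)) / cc$a_px
        v <- (-dx * sin(cc$theta) + dy * cos(cc$theta)) / cc$b_px
        inside <- u * u + v * v <= 1
        if (!any(inside)) next
        for (ch in 1:3) {
          plane <- px[, , ch]
          plane[inside] <- col[ch]
          px[, , ch] <- plane
        }
        if (cells$population[i] == "cb") {
          w <- which(inside, arr.ind = TRUE)
          x0 <- min(w[, 2]) - 1L; x1 <- max(w[, 2]) - 1L
          y0 <- min(w[, 1]) - 1L; y1 <- max(w[, 1]) - 1L
          gt <- rbind(gt, boxes(CB_CLASS,
                                cx = (x0 + x1 + 1) / 2 / S,
                                cy = (y0 + y1 + 1) / 2 / S,
                                w = (x1 - x0 + 1) / S,
                                h = (y1 - y0 + 1) / S))
        }
      }
    }
    if (spec$noise_sd > 0)
      px <- px + array(rnorm(length(px), 0, spec$noise_sd), dim(px))
    list(patch = patch(px, um_per_px = spec$um_per_px), gt = gt,
         cells = cells)
  })
}

# sample cell geometry; rejection sampling keeps cells disjoint when
# required, with whole-scene restarts so an unlucky early placement cannot
# wedge the rest of the packing
plan_cells <- function(spec, restarts = 40L, tries_per_cell = 200L) {
  S <- spec$size_px
  n <- spec$n_cb + spec$n_other
  empty <- data.frame(population = character(), cx_px = numeric(),
                      cy_px = numeric(), a_px = numeric(), b_px = numeric(),
                      theta = numeric(), equiv_diameter_um = numeric(),
                      axis_ratio = numeric())
  if (n == 0) return(empty)
  for (attempt in seq_len(restarts)) {
    rows <- list()
    failed <- FALSE
    for (i in seq_len(n)) {
      is_cb <- i <= spec$n_cb
      pop <- if (is_cb) "cb" else if (runif(1) < 0.5) "small" else "elongated"
      if (pop == "cb") {
        d_um <- runif(1, spec$cb_diameter_um[1], spec$cb_diameter_um[2])
        ratio <- runif(1, 1.0, 1.25)
      } else if (pop == "small") {
        d_um <- runif(1, spec$other_diameter_um[1], spec$other_diameter_um[2])
        ratio <- runif(1, 1.0, 1.25)
      } else {
        d_um <- runif(1, spec$elong_diameter_um[1], spec$elong_diameter_um[2])
        ratio <- runif(1, spec$elong_aspect[1], spec$elong_aspect[2])
      }
      # equal-area ellipse: a*b = r_eq^2, a/b = ratio
      r_eq <- d_um / 2 / spec$um_per_px
      a <- r_eq * sqrt(ratio); b <- r_eq / sqrt(ratio)
      theta <- runif(1, 0, pi)
      margin <- a + 2
      if (2 * margin >= S - 1) { failed <- TRUE; break } # cell exceeds patch
      placed <- FALSE
      for (try in seq_len(tries_per_cell)) {
        cx <- runif(1, margin, S - 1 - margin)
        cy <- runif(1, margin, S - 1 - margin)
        if (!spec$overlap_allowed && length(rows)) {
          prev <- do.call(rbind, rows)
          dmin <- sqrt((prev$cx_px - cx)^2 + (prev$cy_px - cy)^2)
          if (any(dmin < prev$a_px + a + 4)) next
        }
        rows[[length(rows) + 1]] <-
          data.frame(population = pop, cx_px = cx, cy_px = cy, a_px = a,
                     b_px = b, theta = theta, equiv_diameter_um = d_um,
                     axis_ratio = ratio)
        placed <- TRUE
        break
      }
      if (!placed) { failed <- TRUE; break }
    }
    if (!failed) return(do.call(rbind, rows))
  }
  stop("could not place ", n, " cells without overlap in a ", S, "x", S,
       " patch after ", restarts, " restarts; reduce counts, shrink ",
       "diameters, or allow overlap")
}

# low-frequency multiplicative field: coarse gaussian grid, bilinear upsample
smooth_field <- function(size, amp, grid = 8L) {
  if (amp <= 0) return(matrix(1, size, size))
  g <- matrix(rnorm(grid * grid), grid, grid)
  xi <- seq(1, grid, length.out = size)
  x0 <- pmin(floor(xi), grid - 1); fx <- xi - x0
  rowi <- g[x0, , drop = FALSE] * (1 - fx) + g[x0 + 1, , drop = FALSE] * fx
  up <- rowi[, x0, drop = FALSE] * rep(1 - fx, each = size) +
    rowi[, x0 + 1, drop = FALSE] * rep(fx, each = size)
  1 + amp * up / max(abs(up), 1e-9)
}

#' Detection-perturbation specification
#'
#' Turns ground truth into simulated detector output for exercising the
#' metric and mining code: each box is dropped with probability `miss_rate`,
#' survivors are jittered (center and size, Gaussian, `jitter_sd` px) and get
#' a confidence drawn from `tp_conf`; spurious boxes are added at a Poisson
#' rate of `fp_rate` per image with confidences from `fp_conf`.
#'
#' @param miss_rate,fp_rate probabilities / Poisson rate per image.
#' @param jitter_sd center/size noise in pixels.
#' @param tp_conf,fp_conf length-2 uniform confidence ranges for surviving
#'   true boxes and spurious boxes.
#' @param seed integer seed.
#' @return A list of class `cb_perturb_spec`.
#' @export
perturb_spec <- function(miss_rate = 0.1, fp_rate = 1.0, jitter_sd = 2,
                         tp_conf = c(0.6, 1.0), fp_conf = c(0.1, 0.6),
                         seed = 1L) {
  stopifnot(miss_rate >= 0, miss_rate <= 1, fp_rate >= 0, jitter_sd >= 0)
  structure(list(miss_rate = miss_rate, fp_rate = fp_rate,
                 jitter_sd = jitter_sd, tp_conf = tp_conf, fp_conf = fp_conf,
                 seed = as.integer(seed)),
            class = "cb_perturb_spec")
}

#' Simulate detector output from ground truth
#'
#' @param gts ground-truth boxes (class 0), optionally with an `image`
#'   column; perturbation is applied per image.
#' @param spec a [perturb_spec()].
#' @param size_px image side length in px, used to normalize the jitter.
#' @return A detection box `data.frame` with confidences.
#' @export
perturb_detections <- function(gts, spec, size_px = 512L) {
  stopifnot(inherits(spec, "cb_perturb_spec"))
  with_seed(spec$seed, {
    has_img <- !is.null(gts$image)
    imgs <- if (has_img) unique(gts$image) else ""
    out <- list()
    for (img in imgs) {
      g <- if (has_img) gts[gts$image == img, , drop = FALSE] else gts
      keep <- runif(nrow(g)) >= spec$miss_rate
      d <- g[keep, , drop = FALSE]
      if (nrow(d)) {
        j <- spec$jitter_sd / size_px
        d$cx <- pmin(pmax(d$cx + rnorm(nrow(d), 0, j), 0), 1)
        d$cy <- pmin(pmax(d$cy + rnorm(nrow(d), 0, j), 0), 1)
        d$w <- pmin(pmax(d$w + rnorm(nrow(d), 0, j), 2 / size_px), 1)
        d$h <- pmin(pmax(d$h + rnorm(nrow(d), 0, j), 2 / size_px), 1)
        d$confidence <- runif(nrow(d), spec$tp_conf[1], spec$tp_conf[2])
      }
      n_fp <- rpois(1, spec$fp_rate)
      if (n_fp > 0) {
        wref <- if (nrow(g)) mean(g$w) else 0.08
        href <- if (nrow(g)) mean(g$h) else 0.08
        w <- pmin(pmax(wref * exp(rnorm(n_fp, 0, 0.2)), 2 / size_px), 0.5)
        h <- pmin(pmax(href * exp(rnorm(n_fp, 0, 0.2)), 2 / size_px), 0.5)
        fp <- boxes(CB_CLASS,
                    cx = runif(n_fp, w / 2, 1 - w / 2),
                    cy = runif(n_fp, h / 2, 1 - h / 2),
                    w = w, h = h,
                    confidence = runif(n_fp, spec$fp_conf[1], spec$fp_conf[2]))
        if (!is.null(gts$image)) fp$image <- img
        d <- rbind(d, fp)
      }
      out[[length(out) + 1]] <- d
    }
    res <- do.call(rbind, out)
    if (is.null(res)) res <- boxes()
    rownames(res) <- NULL
    res
  })
}

#' Simulate a dataset on disk in the YOLO directory layout
#'
#' Writes `images/*.png` and `labels/*.txt` for `n_images` patches rendered
#' from a base scene specification; each image gets a distinct seed derived
#' from the base seed.
#'
#' @param out_dir output directory (created).
#' @param n_images number of patches.
#' @param base_spec a [scene_spec()] used as the template.
#' @return The ids of the generated images, invisibly.
#' @export
simulate_dataset <- function(out_dir, n_images = 10L,
                             base_spec = scene_spec()) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "labels"), recursive = TRUE,
             showWarnings = FALSE)
  ids <- sprintf("sim%04d", seq_len(n_images))
  for (i in seq_len(n_images)) {
    sp <- base_spec
    sp$seed <- (base_spec$seed + 7919L * i) %% .Machine$integer.max
    sc <- generate_patch(sp)
    write_patch(sc$patch, file.path(out_dir, "images", paste0(ids[i], ".png")))
    write_yolo_labels(sc$gt, file.path(out_dir, "labels",
                                       paste0(ids[i], ".txt")))
  }
  invisible(ids)
}
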