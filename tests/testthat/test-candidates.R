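# render simple dark shapes on a light background for segmentation tests
shape_patch <- function(S, draw) {
  xs <- matrix(rep(0:(S - 1), each = S), S, S)
  ys <- matrix(rep(0:(S - 1), times = S), S, S)
  inside <- draw(xs, ys)
  img <- array(230L, c(S, S, 3))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[inside] <- 70L
    img[, , ch] <- plane
  }
  list(patch = patch(img), inside = inside)
}

test_that("segmentation recovers disjoint disks with near-analytic areas", {
  sp <- shape_patch(220, function(xs, ys)
    ((xs - 60)^2 + (ys - 60)^2 <= 20^2) |
      ((xs - 150)^2 + (ys - 150)^2 <= 30^2))
  cts <- segment_cells(sp$patch)
  expect_length(cts, 2)
  areas <- sort(vapply(cts, function(ct) ct$area_px2, 1.0))
  expect_lt(abs(areas[1] - pi * 20^2) / (pi * 20^2), 0.05)
  expect_lt(abs(areas[2] - pi * 30^2) / (pi * 30^2), 0.05)

  # blank patch -> no contours
  expect_length(segment_cells(patch(array(200L, c(64, 64, 3)))), 0)

  # externally supplied label mask: pass-through contract
  lab <- matrix(0L, 40, 40)
  lab[5:10, 5:10] <- 1L; lab[20:30, 20:26] <- 2L; lab[35:38, 2:6] <- 3L
  expect_length(segment_cells(patch(array(0L, c(40, 40, 3))),
                              label_mask = lab), 3)
})

test_that("equivalent diameter follows the closed form", {
  expect_equal(equivalent_diameter_um(0), 0)
  # disk of radius 50 px at 0.12 um/px: diameter 100 px = 12 um
  expect_equal(equivalent_diameter_um(pi * 50^2, 0.12), 12)
  expect_error(equivalent_diameter_um(-1), "non-negative")

  # inverting the formula at the 5.13 um threshold: min area ~ 1.435e3 px^2
  a_min <- pi * (5.13 / 2 / 0.12)^2
  expect_equal(a_min, 1435, tolerance = 1e-3)
  expect_lt(equivalent_diameter_um(a_min * 0.99), 5.13)
  expect_gt(equivalent_diameter_um(a_min * 1.01), 5.13)

  # strictly increasing in area, linear in um_per_px
  d <- equivalent_diameter_um(c(100, 200, 400))
  expect_true(all(diff(d) > 0))
  expect_equal(equivalent_diameter_um(300, 0.24),
               2 * equivalent_diameter_um(300, 0.12))
})

test_that("aspect ratio from the fitted rotated rectangle", {
  # axis-aligned square
  sq <- contours_from_labels(matrix(as.integer(
    (row(matrix(0, 60, 60)) %in% 20:40) & (col(matrix(0, 60, 60)) %in% 20:40)),
    60, 60))
  expect_equal(aspect_ratio(sq[[1]]), 1.0, tolerance = 1e-9)

  # 80x40 rectangle: ratio 2 or 0.5 depending on fitted order
  m <- matrix(0L, 120, 120)
  m[41:80, 21:100] <- 1L # 40 rows x 80 cols
  rect <- contours_from_labels(m)
  r <- aspect_ratio(rect[[1]])
  expect_true(abs(r - 2) < 1e-6 || abs(r - 0.5) < 1e-6)

  # rasterized circle: ratio 1 within discretization tolerance
  S <- 100
  circ <- shape_patch(S, function(xs, ys) (xs - 50)^2 + (ys - 50)^2 <= 30^2)
  ct <- segment_cells(circ$patch, opening_radius = 0)
  expect_equal(aspect_ratio(ct[[1]]), 1.0, tolerance = 0.05)
})

test_that("filter keeps large round cells and reports failure reasons", {
  crit <- candidate_criteria()
  mk_disk <- function(r_px) {
    S <- max(64, 4 * r_px)
    sp <- shape_patch(S, function(xs, ys)
      (xs - S / 2)^2 + (ys - S / 2)^2 <= r_px^2)
    segment_cells(sp$patch, opening_radius = 0)[[1]]
  }
  # radius 30 px -> 7.2 um, ratio 1: kept
  fc <- filter_candidates(list(mk_disk(30)), crit)
  expect_true(fc$verdicts$kept)
  expect_equal(fc$verdicts$reason, "ok")
  expect_equal(fc$verdicts$equiv_diameter_um, 7.2, tolerance = 0.03)

  # radius 15 px -> 3.6 um: rejected on diameter
  fc2 <- filter_candidates(list(mk_disk(15)), crit)
  expect_false(fc2$verdicts$kept)
  expect_equal(fc2$verdicts$reason, "diameter")

  # 100x40 ellipse: big enough but elongated -> rejected on aspect ratio
  S <- 240
  sp3 <- shape_patch(S, function(xs, ys)
    ((xs - 120) / 50)^2 + ((ys - 120) / 20)^2 <= 1)
  fc3 <- filter_candidates(segment_cells(sp3$patch), crit)
  expect_false(fc3$verdicts$kept)
  expect_equal(fc3$verdicts$reason, "aspect_ratio")
})

test_that("filter verdicts are invariant to doubling the resolution", {
  for (r in c(18, 25, 40)) {
    lo <- shape_patch(200, function(xs, ys)
      (xs - 100)^2 + (ys - 100)^2 <= r^2)
    hi <- shape_patch(400, function(xs, ys)
      (xs - 200)^2 + (ys - 200)^2 <= (2 * r)^2)
    v_lo <- filter_candidates(segment_cells(lo$patch),
                              candidate_criteria(um_per_px = 0.12))$verdicts
    v_hi <- filter_candidates(segment_cells(hi$patch),
                              candidate_criteria(um_per_px = 0.06))$verdicts
    expect_equal(v_lo$kept, v_hi$kept, info = paste("radius", r))
    expect_equal(v_lo$equiv_diameter_um, v_hi$equiv_diameter_um,
                 tolerance = 0.05)
  }
})

test_that("baseline detector: blank patch, closed loop, threshold confidence", {
  expect_equal(nrow(baseline_detect(patch(array(220L, c(64, 64, 3))))), 0)

  # 5 qualifying disks, no clutter: 5 detections, each IoU >= 0.8 to its gt
  sc <- generate_patch(scene_spec(n_cb = 5, n_other = 0, size_px = 384,
                                  noise_sd = 0, seed = 42))
  d <- baseline_detect(sc$patch)
  expect_equal(nrow(d), 5)
  M <- cbdetect:::iou_matrix(d, sc$gt)
  expect_true(all(apply(M, 2, max) >= 0.8))

  # confidence is monotone in diameter and 0.5 exactly at the threshold
  expect_equal(pmin(pmax(5.13 / (2 * 5.13), 0), 1), 0.5)
  expect_true(all(diff(d$confidence[order(d$w * d$h)]) >= 0))
})

test_that("enlarging a kept circular contour never flips the diameter verdict", {
  crit <- candidate_criteria()
  prev_kept <- FALSE
  for (r in seq(22, 50, 4)) {
    S <- max(128, 4 * r)
    sp <- shape_patch(S, function(xs, ys)
      (xs - S / 2)^2 + (ys - S / 2)^2 <= r^2)
    v <- filter_candidates(segment_cells(sp$patch), crit)$verdicts
    if (prev_kept) expect_true(v$pass_diameter, info = paste("radius", r))
    prev_kept <- prev_kept || v$kept
  }
  expect_true(prev_kept)
})
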