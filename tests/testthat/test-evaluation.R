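test_that("iou basics: identity, disjoint, hand-computed overlap", {
  a <- boxes(0, .5, .5, .2, .2)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(boxes(0, .1, .1, .1, .1), boxes(0, .8, .8, .1, .1)), 0)
  # corner frame (0,0,10,10) vs (5,0,15,10) on a 20-unit canvas: 50/150
  b1 <- boxes(0, cx = 5 / 20, cy = 5 / 20, w = 10 / 20, h = 10 / 20)
  b2 <- boxes(0, cx = 10 / 20, cy = 5 / 20, w = 10 / 20, h = 10 / 20)
  expect_equal(iou(b1, b2), 1 / 3)
})

test_that("matching is greedy by confidence and one-to-one", {
  gt <- boxes(0, .5, .5, .2, .2)
  # one det, IoU ~ .6 to the sole gt
  d1 <- boxes(0, .5 + 0.024, .5, .2, .2, confidence = .9)
  stopifnot(iou(d1, gt) > 0.5)
  m <- match_detections(d1, gt, 0.5)
  expect_true(m$is_tp)
  expect_length(m$fn, 0)

  # IoU below threshold: FP + FN
  d2 <- boxes(0, .5 + 0.09, .5, .2, .2, confidence = .9)
  stopifnot(iou(d2, gt) < 0.5)
  m2 <- match_detections(d2, gt, 0.5)
  expect_false(any(m2$is_tp))
  expect_equal(m2$fn, 1L)

  # two dets over the same gt: higher confidence wins, the other is FP even
  # though its IoU is larger
  d3 <- rbind(boxes(0, .5 + 0.024, .5, .2, .2, confidence = .9),
              boxes(0, .5 + 0.005, .5, .2, .2, confidence = .8))
  m3 <- match_detections(d3, gt, 0.5)
  expect_equal(m3$order, c(1L, 2L))
  expect_equal(m3$is_tp, c(TRUE, FALSE))
})

test_that("cross-image detections never match", {
  gt <- boxes(0, .5, .5, .2, .2, image = "a")
  d <- boxes(0, .5, .5, .2, .2, confidence = .9, image = "b")
  m <- match_detections(d, gt, 0.5)
  expect_false(any(m$is_tp))
})

test_that("precision/recall: scalars, cumulative points and edge cases", {
  gt <- boxes(0, c(.2, .7), c(.2, .7), .1, .1)
  # detections identical to ground truth
  m <- match_detections(transform(gt, confidence = 1), gt, 0.5)
  pr <- precision_recall(m)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)

  # no detections, gts exist
  pr0 <- precision_recall(match_detections(boxes(), gt, 0.5))
  expect_equal(pr0$recall, 0)

  # sequence (TP, FP, TP) with n_gt = 2 -> (.5,1), (.5,.5), (1,2/3)
  d <- rbind(boxes(0, .2, .2, .1, .1, confidence = .9),
             boxes(0, .45, .45, .1, .1, confidence = .8),
             boxes(0, .7, .7, .1, .1, confidence = .7))
  pr3 <- precision_recall(match_detections(d, gt, 0.5))
  expect_equal(pr3$pr_points$recall, c(.5, .5, 1))
  expect_equal(pr3$pr_points$precision, c(1, .5, 2 / 3))

  # no gt, no detections: defined as 1/1; detections without gt: recall NA
  prv <- precision_recall(match_detections(boxes(), boxes(), 0.5))
  expect_equal(c(prv$precision, prv$recall), c(1, 1))
  prna <- precision_recall(match_detections(
    boxes(0, .5, .5, .1, .1, confidence = .5), boxes(), 0.5))
  expect_true(prna$recall_undefined)
})

test_that("AP: perfect, empty, and the hand-worked staircase", {
  gt <- boxes(0, c(.2, .7), c(.2, .7), .1, .1)
  expect_equal(average_precision(transform(gt, confidence = 1), gt), 1)
  expect_equal(average_precision(boxes(), gt), 0)
  d <- rbind(boxes(0, .2, .2, .1, .1, confidence = .9),
             boxes(0, .45, .45, .1, .1, confidence = .8),
             boxes(0, .7, .7, .1, .1, confidence = .7))
  expect_equal(average_precision(d, gt), 0.5 * 1 + 0.5 * (2 / 3),
               tolerance = 1e-9)
})

test_that("AP equals the brute-force oracle on randomized small instances", {
  set.seed(77)
  for (k in 1:200) {
    inst <- random_instance()
    if (nrow(inst$gts) == 0) next
    thr <- sample(c(.3, .5, .7), 1)
    expect_equal(average_precision(inst$dets, inst$gts, thr),
                 oracle_ap(inst$dets, inst$gts, thr),
                 tolerance = 1e-12, info = paste("instance", k))
  }
})

test_that("mAP over the ladder: perfect sets, partial overlap, single class", {
  gt <- boxes(0, c(.25, .7), c(.25, .7), .12, .12)
  ev <- mean_ap(transform(gt, confidence = 1), gt)
  expect_equal(ev$map50, 1)
  expect_equal(ev$map_overall, 1)

  # single det at IoU ~ 0.62: AP 1 for thresholds {.50,.55,.60}, 0 above
  gt1 <- boxes(0, .5, .5, .2, .2)
  off <- 0.2 * (1 - 0.62) / (1 + 0.62) # shift giving IoU = 0.62 exactly
  d1 <- boxes(0, .5 + off, .5, .2, .2, confidence = .9)
  expect_equal(iou(d1, gt1), 0.62, tolerance = 1e-12)
  ev1 <- mean_ap(d1, gt1)
  expect_equal(unname(ev1$ap_per_threshold[1, ]),
               c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(ev1$map_overall, 0.3)

  # with a single class, per-threshold mAP equals the class AP
  expect_equal(unname(ev1$map_per_threshold), unname(ev1$ap_per_threshold[1, ]))
})

test_that("two-class mAP averages per-class APs", {
  gt <- rbind(boxes(0, .25, .25, .1, .1), boxes(1, .75, .75, .1, .1))
  # class 0 detected perfectly, class 1 missed
  d <- boxes(0, .25, .25, .1, .1, confidence = 1)
  ev <- mean_ap(d, gt, 0.5)
  expect_equal(unname(ev$ap_per_threshold[, 1]), c(1, 0))
  expect_equal(ev$map50, 0.5)
})

test_that("metrics lie in [0,1] and are invariant to rigid box transforms", {
  set.seed(99)
  for (k in 1:20) {
    inst <- random_instance()
    if (nrow(inst$gts) == 0) next
    ev <- mean_ap(inst$dets, inst$gts)
    expect_true(all(ev$ap_per_threshold >= 0 & ev$ap_per_threshold <= 1))
    # uniform shrink towards the origin: IoUs unchanged
    shrink <- function(b) transform(b, cx = cx / 2, cy = cy / 2,
                                    w = w / 2, h = h / 2)
    ev2 <- mean_ap(shrink(inst$dets), shrink(inst$gts))
    expect_equal(ev$map_overall, ev2$map_overall, tolerance = 1e-12)
  }
})

test_that("AP is non-increasing in the IoU threshold (empirical property)", {
  set.seed(123)
  violations <- 0
  for (k in 1:50) {
    inst <- random_instance()
    if (nrow(inst$gts) == 0 || nrow(inst$dets) == 0) next
    aps <- vapply(seq(50, 95, 5) / 100, function(t)
      average_precision(inst$dets, inst$gts, t), 1.0)
    if (any(diff(aps) > 1e-12)) violations <- violations + 1
  }
  # greedy matching does not guarantee monotonicity universally, but on
  # jitter-style instances it should hold essentially always
  expect_lte(violations, 2)
})

test_that("directory evaluation matches in-memory evaluation", {
  root <- withr::local_tempdir()
  gt <- boxes(0, c(.2, .6), c(.2, .6), .1, .1, image = c("a", "a"))
  d <- transform(gt, confidence = c(.9, .8))
  write_label_dir(gt, file.path(root, "labels"))
  write_label_dir(d, file.path(root, "predictions"))
  ev <- evaluate_dirs(file.path(root, "labels"), file.path(root, "predictions"))
  expect_equal(ev$map50, mean_ap(d, gt, 0.5)$map50)
  expect_equal(ev$map50, 1)
})
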