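test_that("tiling lays a regular grid and drops partial edge tiles", {
  img <- array(sample(0:255, 1024 * 1024 * 3, TRUE), c(1024, 1024, 3))
  tiles <- tile_image(img, 512)
  expect_length(tiles, 4)
  origins <- t(vapply(tiles, function(t) t$origin_xy, c(0L, 0L)))
  expect_setequal(paste(origins[, 1], origins[, 2]),
                  c("0 0", "512 0", "0 512", "512 512"))

  # single exact tile is the identity
  img2 <- array(sample(0:255, 512 * 512 * 3, TRUE), c(512, 512, 3))
  t2 <- tile_image(img2, 512)
  expect_length(t2, 1)
  expect_identical(t2[[1]]$pixels, array(as.integer(img2), dim(img2)))

  # 1000x700: floor(1000/512) x floor(700/512) = 1 tile at the origin
  img3 <- array(0L, c(700, 1000, 3))
  t3 <- tile_image(img3, 512)
  expect_length(t3, 1)
  expect_identical(t3[[1]]$origin_xy, c(0L, 0L))

  # smaller than the tile in one dimension: empty, not an error
  expect_length(tile_image(array(0L, c(100, 1000, 3)), 512), 0)
})

test_that("tiles reassemble the covered region pixel-for-pixel", {
  set.seed(11)
  img <- array(sample(0:255, 300 * 460 * 3, TRUE), c(300, 460, 3))
  ts <- 128L
  tiles <- tile_image(img, ts)
  recon <- array(NA_integer_, dim(img))
  for (t in tiles) {
    x0 <- t$origin_xy[1]; y0 <- t$origin_xy[2]
    recon[(y0 + 1):(y0 + ts), (x0 + 1):(x0 + ts), ] <- t$pixels
    expect_identical(dim(t$pixels), c(ts, ts, 3L))
  }
  covered <- !is.na(recon)
  expect_identical(recon[covered], array(as.integer(img), dim(img))[covered])
  # non-overlapping: each covered pixel written exactly once
  expect_equal(sum(covered), length(tiles) * ts * ts * 3)
})

test_that("YOLO label reading parses fields and rejects bad lines", {
  b <- read_yolo_labels("0 0.5 0.5 0.1 0.2")
  expect_equal(nrow(b), 1)
  expect_equal(b$class_id, 0L)
  expect_equal(unlist(b[1, c("cx", "cy", "w", "h")], use.names = FALSE),
               c(.5, .5, .1, .2))
  expect_true(is.na(b$confidence))

  expect_equal(nrow(read_yolo_labels(character())), 0)

  expect_warning(bad <- read_yolo_labels(c("0 0.5 0.5 0.1 0.2",
                                           "0 1.5 0.5 0.1 0.2")),
                 "line 2")
  expect_equal(nrow(bad), 1)
  expect_warning(read_yolo_labels("0 0.5 0.5 -0.1 0.2"), "line 1")

  # confidence auto-detected per line
  conf <- read_yolo_labels("1 0.3 0.4 0.1 0.1 0.75")
  expect_equal(conf$confidence, 0.75)
  expect_equal(conf$class_id, 1L)
})

test_that("write/read round-trips box sequences", {
  expect_length(write_yolo_labels(boxes()), 0)
  b <- boxes(c(0L, 1L), cx = c(0.125, 0.5), cy = c(0.25, 0.75),
             w = c(0.1, 0.2), h = c(0.05, 0.4), confidence = c(NA, 0.875))
  lines <- write_yolo_labels(b)
  expect_length(lines, 2)
  back <- read_yolo_labels(lines)
  expect_equal(back, b)
  # bit-exact second round trip
  expect_identical(write_yolo_labels(back), lines)
})

test_that("label directory I/O pairs files by basename", {
  d <- withr::local_tempdir()
  b <- boxes(0L, cx = c(.2, .6, .4), cy = c(.2, .6, .4), w = .1, h = .1,
             image = c("a", "a", "b"))
  write_label_dir(b, d, images = c("a", "b", "empty"))
  expect_setequal(list.files(d), c("a.txt", "b.txt", "empty.txt"))
  back <- read_label_dir(d)
  expect_equal(sum(back$image == "a"), 2)
  expect_equal(sum(back$image == "b"), 1)
})

test_that("split sizes follow the ceiling convention and are deterministic", {
  ids <- sprintf("im%04d", 1:1205)
  s <- split_dataset(ids, 0.05, 0.8, seed = 123)
  expect_equal(lengths(s)[c("train", "validate", "test")],
               c(train = 915L, validate = 229L, test = 61L))

  s100 <- split_dataset(as.character(1:100), 0.05, 0.8, seed = 9)
  expect_equal(lengths(s100)[c("train", "validate", "test")],
               c(train = 76L, validate = 19L, test = 5L))

  # determinism and permutation invariance of membership
  s2 <- split_dataset(ids, 0.05, 0.8, seed = 123)
  expect_identical(s, s2)
  s3 <- split_dataset(rev(ids), 0.05, 0.8, seed = 123)
  expect_setequal(s$test, s3$test)
  expect_setequal(s$validate, s3$validate)

  expect_error(split_dataset(c("a", "b"), seed = 1), "at least 3")
})

test_that("split sizes match direct arithmetic for many n (property)", {
  for (n in c(3:12, 50, 99, 100, 101, 777, 1205)) {
    s <- split_dataset(as.character(seq_len(n)), 0.05, 0.8, seed = 4)
    n_test <- ceiling(0.05 * n)
    n_val <- ceiling(0.2 * (n - n_test))
    expect_equal(length(s$test), n_test, info = paste("n =", n))
    expect_equal(length(s$validate), n_val, info = paste("n =", n))
    expect_equal(length(s$train), n - n_test - n_val, info = paste("n =", n))
    # disjoint and exhaustive
    expect_setequal(c(s$train, s$validate, s$test), as.character(seq_len(n)))
    expect_equal(anyDuplicated(c(s$train, s$validate, s$test)), 0)
  }
})

test_that("grouped split keeps groups together", {
  ids <- sprintf("p%02d_img%02d", rep(1:10, each = 8), 1:8)
  grp <- rep(sprintf("p%02d", 1:10), each = 8)
  s <- split_dataset(ids, 0.2, 0.75, seed = 2, group = grp)
  part_of <- function(id) names(which(vapply(s, function(v) id %in% v, TRUE)))
  for (g in unique(grp)) {
    members <- ids[grp == g]
    expect_length(unique(vapply(members, part_of, "")), 1)
  }
})

test_that("dataset accounting counts images and per-class labels", {
  mk <- function(n_cb, n_noncb, prefix) {
    n <- n_cb + n_noncb
    boxes(rep(c(0L, 1L), c(n_cb, n_noncb)),
          cx = runif(n, .3, .7), cy = runif(n, .3, .7), w = .1, h = .1,
          image = paste0(prefix, seq_len(n)))
  }
  set.seed(5)
  labels <- list(train = mk(12, 4, "t"), validate = mk(5, 2, "v"),
                 test = mk(2, 1, "s"))
  st <- dataset_stats(labels)
  tot <- st$counts[st$counts$partition == "total", ]
  expect_equal(tot$cb_labels, 19)
  expect_equal(tot$noncb_labels, 7)
  expect_true(all(c("min", "mean", "max") %in% colnames(st$box_size)))

  # no labels at all
  empty <- dataset_stats(boxes(image = character()), images = c("x", "y"))
  expect_equal(empty$counts$cb_labels, c(0, 0))
  expect_equal(empty$counts$images[1], 2)
  expect_null(empty$box_size)
})

test_that("orphan label files are diagnosed", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "images")); dir.create(file.path(root, "labels"))
  png::writePNG(array(0.5, c(8, 8, 3)), file.path(root, "images", "a.png"))
  writeLines("0 0.5 0.5 0.1 0.1", file.path(root, "labels", "a.txt"))
  writeLines("0 0.5 0.5 0.1 0.1", file.path(root, "labels", "ghost.txt"))
  expect_warning(orph <- check_pairing(file.path(root, "images"),
                                       file.path(root, "labels")),
                 "ghost")
  expect_equal(orph, "ghost")
})
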