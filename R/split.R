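#' Split a dataset into train / validate / test partitions
#'
#' The test partition is carved out first as `ceil(test_frac * n)` ids; the
#' remainder is then divided so that validation gets
#' `ceil((1 - train_frac_of_rest) * rest)` and training the rest. This ceiling
#' convention is the one that turns 1,205 images at a 5% test split and an
#' 80-20 train-validation division into partitions of 915 / 229 / 61.
#' Membership is a seeded uniform shuffle, so the split is a
#' permutation-invariant function of the id set and the seed.
#'
#' @param ids character or integer vector of image identifiers (n >= 3).
#' @param test_frac fraction of all ids reserved for testing (default 0.05).
#' @param train_frac_of_rest fraction of the non-test ids used for training
#'   (default 0.8).
#' @param seed integer RNG seed.
#' @param group optional vector parallel to `ids` (e.g. patient or slide id);
#'   when given, all ids sharing a group land in the same partition and the
#'   fractions apply at the group level, guarding against leakage across
#'   partitions.
#' @return A list of class `cb_split` with components `train`, `validate`,
#'   `test`: disjoint vectors whose union is `ids`.
#' @examples
#' s <- split_dataset(sprintf("img%04d", 1:1205), seed = 1)
#' lengths(s) # 915, 229, 61
#' @export
split_dataset <- function(ids, test_frac = 0.05, train_frac_of_rest = 0.8,
                          seed = 1L, group = NULL) {
  stopifnot(test_frac > 0, test_frac < 1,
            train_frac_of_rest > 0, train_frac_of_rest < 1,
            anyDuplicated(ids) == 0)
  units <- if (is.null(group)) as.character(ids) else unique(as.character(group))
  n <- length(units)
  if (n < 3) stop("need at least 3 ", if (is.null(group)) "ids" else "groups",
                  " to form three partitions")
  n_test <- as.integer(ceiling(test_frac * n))
  n_val <- as.integer(ceiling((1 - train_frac_of_rest) * (n - n_test)))
  n_train <- n - n_test - n_val
  if (n_train < 1) stop("degenerate split: no training units left")
  perm <- with_seed(seed, sample(sort(units)))
  assign_unit <- rep(c("test", "validate", "train"),
                     c(n_test, n_val, n_train))[match(units, perm)]
  if (is.null(group)) {
    assign_id <- assign_unit[match(as.character(ids), units)]
  } else {
    assign_id <- assign_unit[match(as.character(group), units)]
  }
  structure(list(train = ids[assign_id == "train"],
                 validate = ids[assign_id == "validate"],
                 test = ids[assign_id == "test"]),
            class = "cb_split")
}

#' @export
print.cb_split <- function(x, ...) {
  cat(sprintf("<cb_split train=%d validate=%d test=%d>\n",
              length(x$train), length(x$validate), length(x$test)))
  invisible(x)
}

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  expr
}

#' Dataset accounting
#'
#' Counts images and per-class labels for each partition of a dataset and
#' summarizes bounding-box sizes. Input is either a single box `data.frame`
#' with an `image` column, or a named list of such frames (one per partition,
#' e.g. the output of splitting); image ids present in `images` but absent
#' from the labels count as label-free images.
#'
#' @param labels a box `data.frame` with an `image` column, or a named list of
#'   them keyed by partition.
#' @param images optional character vector (or list per partition) of all
#'   image ids, including label-free ones.
#' @return A list with `counts` (data.frame: partition, images, cb_labels,
#'   noncb_labels, with a `total` row) and `box_size` (min/quartiles/mean/max
#'   of normalized widths and heights over all labels).
#' @export
dataset_stats <- function(labels, images = NULL) {
  if (is.data.frame(labels)) labels <- list(all = labels)
  if (!is.null(images) && !is.list(images)) images <- list(all = images)
  parts <- names(labels)
  rows <- lapply(parts, function(p) {
    b <- labels[[p]]
    imgs <- unique(c(if (nrow(b)) unique(b$image), images[[p]]))
    data.frame(partition = p, images = length(imgs),
               cb_labels = sum(b$class_id == CB_CLASS),
               noncb_labels = sum(b$class_id == NONCB_CLASS))
  })
  counts <- do.call(rbind, rows)
  counts <- rbind(counts, data.frame(partition = "total",
                                     images = sum(counts$images),
                                     cb_labels = sum(counts$cb_labels),
                                     noncb_labels = sum(counts$noncb_labels)))
  all_b <- do.call(rbind, unname(labels))
  box_size <- if (!is.null(all_b) && nrow(all_b)) {
    sz <- function(v) c(min = min(v), q25 = unname(quantile(v, .25)),
                        median = unname(quantile(v, .5)), mean = mean(v),
                        q75 = unname(quantile(v, .75)), max = max(v))
    rbind(width = sz(all_b$w), height = sz(all_b$h))
  } else NULL
  list(counts = counts, box_size = box_size)
}

#' Check image/label pairing in a YOLO-layout directory pair
#'
#' @param images_dir,labels_dir directories paired by shared basenames.
#' @return Character vector of label basenames with no matching image
#'   (empty when consistent); a diagnostic warning is raised for each.
#' @export
check_pairing <- function(images_dir, labels_dir) {
  imgs <- tools::file_path_sans_ext(list.files(images_dir, pattern = "\\.png$"))
  labs <- tools::file_path_sans_ext(list.files(labels_dir, pattern = "\\.txt$"))
  orphans <- setdiff(labs, imgs)
  for (o in orphans)
    warning("label file '", o, ".txt' has no matching image", call. = FALSE)
  invisible(orphans)
}
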