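#' Pipeline configuration
#'
#' One place for every tunable of the patch-to-grade pipeline, with the
#' source pipeline's operating values as defaults: 5.13 um minimum equivalent
#' diameter, 0.7-1.3 aspect band, 0.12 um/px, IoU 0.5, 5% test split and
#' 80-20 train-validation division. Can be read from / written to YAML.
#'
#' @param out_dir run directory; stage artifacts land in subdirectories.
#' @param stages ordered subset of
#'   `c("simulate", "preprocess", "detect", "evaluate", "mine", "grade")`.
#' @param seed master seed; stage seeds derive from it.
#' @param detector `"baseline"` for the built-in classical detector, or
#'   `"files"` to consume YOLO prediction files from `predictions_dir`.
#' @param predictions_dir directory of prediction files when
#'   `detector = "files"`.
#' @param preprocess_enabled run background removal before detection (the
#'   "preprocessed dataset" arm of the study design); when `FALSE` the raw
#'   images are used (the "default dataset" arm).
#' @param simulate,criteria,preprocess,evaluate,mining,grade named lists of
#'   stage parameters overriding the defaults shown in the function body.
#' @return A list of class `cb_config`.
#' @export
cb_config <- function(out_dir, stages = c("simulate", "preprocess", "detect",
                                          "evaluate", "mine", "grade"),
                      seed = 1L, detector = c("baseline", "files"),
                      predictions_dir = NULL, preprocess_enabled = TRUE,
                      simulate = list(), criteria = list(),
                      preprocess = list(), evaluate = list(),
                      mining = list(), grade = list()) {
  merge_defaults <- function(user, def) utils::modifyList(def, user)
  cfg <- list(
    out_dir = out_dir, stages = stages, seed = as.integer(seed),
    detector = match.arg(detector), predictions_dir = predictions_dir,
    preprocess_enabled = isTRUE(preprocess_enabled),
    simulate = merge_defaults(simulate, list(
      n_images = 8L, n_cb = 5L, n_other = 5L, stain_mode = "purple",
      size_px = 512L, noise_sd = 3)),
    criteria = merge_defaults(criteria, list(
      min_equiv_diameter_um = 5.13, aspect_ratio_lo = 0.7,
      aspect_ratio_hi = 1.3, um_per_px = 0.12)),
    preprocess = merge_defaults(preprocess, list(
      fill_ratio = 0.5, dilate_radius = 2L)),
    evaluate = merge_defaults(evaluate, list(ladder = TRUE)),
    mining = merge_defaults(mining, list(
      iou_threshold = 0.5, cap_ratio = 1.0, band_lo = 0.05, band_hi = 0.95)),
    grade = merge_defaults(grade, list(
      conf_threshold = 0.25, patches_per_hpf = 1L, expected_n_hpf = 10L)))
  class(cfg) <- "cb_config"
  cfg
}

#' @rdname cb_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(cb_config, y)
}

#' @rdname cb_config
#' @param cfg a `cb_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the patch-to-grade pipeline
#'
#' Executes the configured stages in order on a directory dataset laid out as
#' `{images/, labels/, predictions/}`: simulate (synthetic dataset), preprocess
#' (background removal), detect (baseline detector or prediction files),
#' evaluate (mAP against the ground-truth labels), mine (hard negatives into a
#' two-class label set), grade (per-patch CB counts and a WHO grade). Writes
#' per-stage artifacts under `out_dir` and a `manifest.json` recording every
#' resolved parameter and seed, sufficient to reproduce the run; reruns with
#' the same config produce byte-identical metric reports.
#'
#' @param config a [cb_config()] or path to a YAML config.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_config(config) else config
  stopifnot(inherits(cfg, "cb_config"))
  od <- cfg$out_dir
  dir.create(od, recursive = TRUE, showWarnings = FALSE)
  crit <- candidate_criteria(cfg$criteria$min_equiv_diameter_um,
                             c(cfg$criteria$aspect_ratio_lo,
                               cfg$criteria$aspect_ratio_hi),
                             cfg$criteria$um_per_px)
  statuses <- list()
  reports <- list()

  img_dir <- file.path(od, "images")
  lab_dir <- file.path(od, "labels")

  for (stage in cfg$stages) {
    switch(stage,
      simulate = {
        sp <- scene_spec(n_cb = cfg$simulate$n_cb,
                         n_other = cfg$simulate$n_other,
                         stain_mode = cfg$simulate$stain_mode,
                         size_px = cfg$simulate$size_px,
                         um_per_px = cfg$criteria$um_per_px,
                         noise_sd = cfg$simulate$noise_sd,
                         seed = cfg$seed)
        simulate_dataset(od, cfg$simulate$n_images, sp)
      },
      preprocess = {
        if (cfg$preprocess_enabled) {
          if (!dir.exists(img_dir)) stop("stage 'preprocess': missing ", img_dir)
          pp_dir <- file.path(od, "preprocessed")
          dir.create(pp_dir, showWarnings = FALSE)
          pcfg <- preprocess_config(cfg$preprocess$dilate_radius,
                                    cfg$preprocess$fill_ratio)
          for (f in list.files(img_dir, pattern = "\\.png$")) {
            p <- read_patch(file.path(img_dir, f),
                            um_per_px = cfg$criteria$um_per_px)
            write_patch(remove_background(p, pcfg), file.path(pp_dir, f))
          }
        }
      },
      detect = {
        pred_dir <- file.path(od, "predictions")
        if (cfg$detector == "files") {
          if (is.null(cfg$predictions_dir) || !dir.exists(cfg$predictions_dir))
            stop("stage 'detect': detector = 'files' needs predictions_dir")
          dir.create(pred_dir, showWarnings = FALSE)
          file.copy(list.files(cfg$predictions_dir, pattern = "\\.txt$",
                               full.names = TRUE), pred_dir, overwrite = TRUE)
        } else {
          src <- if (cfg$preprocess_enabled &&
                     dir.exists(file.path(od, "preprocessed")))
            file.path(od, "preprocessed") else img_dir
          if (!dir.exists(src)) stop("stage 'detect': missing ", src)
          dir.create(pred_dir, showWarnings = FALSE)
          for (f in list.files(src, pattern = "\\.png$")) {
            p <- read_patch(file.path(src, f),
                            um_per_px = cfg$criteria$um_per_px)
            d <- baseline_detect(p, crit)
            write_yolo_labels(d, file.path(pred_dir,
                                           paste0(tools::file_path_sans_ext(f),
                                                  ".txt")))
          }
        }
      },
      evaluate = {
        pred_dir <- file.path(od, "predictions")
        if (!dir.exists(lab_dir)) stop("stage 'evaluate': missing ", lab_dir)
        if (!dir.exists(pred_dir)) stop("stage 'evaluate': missing ", pred_dir)
        thr <- if (isTRUE(cfg$evaluate$ladder)) seq(50, 95, 5) / 100 else 0.5
        ev <- evaluate_dirs(lab_dir, pred_dir, thr)
        reports$evaluation <- list(
          map50 = ev$map50, map_overall = ev$map_overall,
          map_per_threshold = as.list(ev$map_per_threshold),
          precision = ev$pr50[[1]]$precision, recall = ev$pr50[[1]]$recall)
        jsonlite::write_json(reports$evaluation,
                             file.path(od, "metrics.json"),
                             auto_unbox = TRUE, digits = NA)
      },
      mine = {
        pred_dir <- file.path(od, "predictions")
        if (!dir.exists(lab_dir) || !dir.exists(pred_dir))
          stop("stage 'mine': missing labels/ or predictions/ under ", od)
        gts <- read_label_dir(lab_dir, has_confidence = FALSE)
        dets <- read_label_dir(pred_dir, has_confidence = TRUE)
        mcfg <- mining_config(cfg$mining$iou_threshold, cfg$mining$cap_ratio,
                              c(cfg$mining$band_lo, cfg$mining$band_hi))
        neg <- mine_false_positives(dets, gts, mcfg)
        two <- build_two_class_dataset(gts, neg, mcfg$iou_threshold)
        write_label_dir(two, file.path(od, "labels2"),
                        images = tools::file_path_sans_ext(
                          list.files(lab_dir, pattern = "\\.txt$")))
      },
      grade = {
        pred_dir <- file.path(od, "predictions")
        if (!dir.exists(pred_dir)) stop("stage 'grade': missing ", pred_dir)
        dets <- read_label_dir(pred_dir, has_confidence = TRUE)
        ids <- tools::file_path_sans_ext(list.files(pred_dir,
                                                    pattern = "\\.txt$"))
        counts <- vapply(ids, function(id) {
          d <- if (nrow(dets) && "image" %in% names(dets))
            dets[dets$image == id, , drop = FALSE]
          else dets[0, , drop = FALSE]
          count_cb(d, cfg$grade$conf_threshold)
        }, 1L)
        k <- max(1L, as.integer(cfg$grade$patches_per_hpf))
        hpf <- vapply(split(counts, ceiling(seq_along(counts) / k)), sum, 1L)
        gr <- suppressWarnings(grade_slide(hpf, cfg$grade$expected_n_hpf))
        reports$grade <- list(per_patch = as.list(counts),
                              hpf_counts = as.numeric(hpf),
                              mean_count = gr$mean_count,
                              grade = as.character(gr$grade))
        jsonlite::write_json(reports$grade, file.path(od, "grade.json"),
                             auto_unbox = TRUE, digits = NA)
      },
      stop("unknown stage: ", stage))
    statuses[[stage]] <- "success"
  }

  cfg_file <- tempfile(); on.exit(unlink(cfg_file))
  yaml::write_yaml(unclass(cfg), cfg_file)
  manifest <- list(package = "cbdetect",
                   version = as.character(utils::packageVersion("cbdetect")),
                   config = unclass(cfg),
                   config_md5 = unname(tools::md5sum(cfg_file)),
                   seed = cfg$seed,
                   stages = statuses)
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
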