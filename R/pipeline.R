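#' Default end-to-end pipeline configuration
#'
#' Nested blocks mirror the stage modules: `synth` (generator and dataset
#' size), `detect`, `crop`, `enhance`, `classify`, `evaluate`, plus a global
#' `seed` and optional `output_dir`. Defaults describe a CPU-scale synthetic
#' study: reduced-width networks on moderately sized images with a strong
#' defect contrast.
#'
#' @return A list of class `pipeline_config`.
#' @export
default_pipeline_config <- function() {
  structure(list(
    seed = 1,
    output_dir = NULL,
    synth = list(n_images = 60, damaged_fraction = 0.5,
                 image_width = 160, image_height = 160, n_implants = 1,
                 thread_pitch = 9, shaft_width = 16,
                 shaft_intensity = 205, background_mean = 90,
                 background_noise_sd = 10, defect_depth_threads = 3,
                 defect_darkening = 80, rotation_max_deg = 8, n_teeth = 1),
    detect = list(train_fraction = 0.6, input_size = 160, n_anchors = 5,
                  conf_threshold = 0.5, nms_iou = 0.5,
                  initial_learning_rate = 0.002, max_epoch = 40,
                  mini_batch_size = 8, width_multiplier = 0.125),
    crop = list(margin = 10),
    enhance = list(tiles = c(8, 8), clip_limit = 0.01, range_window = 3),
    classify = list(input_height = 180, input_width = 100,
                    initial_learning_rate = 0.003, max_epoch = 20,
                    mini_batch_size = 16, lr_drop_factor = 0.75,
                    lr_drop_period = 30, dropout_probability = 0.5,
                    width_multiplier = 0.125, train_fraction = 0.8),
    evaluate = list(iou_match = 0.5)
  ), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Accepts a config list or a path to a YAML/JSON file, checks every
#' invariant, and either returns the typed configuration or an object of
#' class `config_violations` listing every violation found (never only the
#' first).
#'
#' @param config A list, `pipeline_config`, or file path.
#' @return A `pipeline_config`, or a `config_violations` character vector.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("validate_config: cannot read ", config)
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  base <- default_pipeline_config()
  for (blk in names(base)) {
    if (is.list(base[[blk]]) && !is.null(config[[blk]]))
      base[[blk]] <- utils::modifyList(base[[blk]], config[[blk]])
    else if (!is.null(config[[blk]])) base[[blk]] <- config[[blk]]
  }
  cfg <- base
  v <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) v <<- c(v, msg)
  chk(cfg$synth$n_images >= 1, "synth.n_images: must be >= 1")
  chk(cfg$synth$damaged_fraction >= 0 && cfg$synth$damaged_fraction <= 1,
      "synth.damaged_fraction: must lie in [0, 1]")
  chk(cfg$synth$image_width >= 128 && cfg$synth$image_height >= 128,
      "synth.image_width/image_height: must be >= 128")
  chk(cfg$synth$shaft_intensity > cfg$synth$background_mean,
      "synth.shaft_intensity: must exceed synth.background_mean")
  chk(cfg$detect$input_size %% 32 == 0, "detect.input_size: must be divisible by 32")
  chk(cfg$detect$train_fraction > 0 && cfg$detect$train_fraction < 1,
      "detect.train_fraction: must lie in (0, 1)")
  chk(cfg$detect$conf_threshold > 0 && cfg$detect$conf_threshold < 1,
      "detect.conf_threshold: must lie in (0, 1)")
  chk(cfg$crop$margin >= 0, "crop.margin: must be >= 0")
  chk(cfg$enhance$clip_limit > 0 && cfg$enhance$clip_limit <= 1,
      "enhance.clip_limit: must lie in (0, 1]")
  chk(cfg$enhance$range_window >= 3 && cfg$enhance$range_window %% 2 == 1,
      "enhance.range_window: must be odd and >= 3")
  chk(cfg$classify$train_fraction > 0 && cfg$classify$train_fraction <= 1,
      "classify.train_fraction: must lie in (0, 1]")
  chk(cfg$classify$initial_learning_rate > 0,
      "classify.initial_learning_rate: must be positive")
  chk(cfg$evaluate$iou_match > 0 && cfg$evaluate$iou_match < 1,
      "evaluate.iou_match: must lie in (0, 1)")
  if (length(v)) return(structure(v, class = "config_violations"))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.config_violations <- function(x, ...) {
  cat("configuration violations:\n")
  for (m in x) cat(" -", m, "\n")
  invisible(x)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

## crop + split + enhance each implant of one image; returns labeled halves
image_to_halves <- function(ai, boxes, cfg, labels_from_truth = TRUE) {
  halves <- list()
  if (is.null(boxes) || nrow(boxes) == 0) return(halves)
  for (b in seq_len(nrow(boxes))) {
    box <- boxes[b, ]
    truth_id <- NA
    if (nrow(ai$boxes) > 0) {
      ious <- vapply(seq_len(nrow(ai$boxes)),
                     function(t) iou_box(box, ai$boxes[t, ]), numeric(1))
      if (max(ious) >= 0.25) truth_id <- ai$boxes$id[which.max(ious)]
    }
    hc <- tryCatch({
      crop <- crop_implant(ai$pixels, box, cfg$crop$margin)
      mask <- binarize_implant(crop)
      line <- fit_midline(mask)
      split_halves(crop, line)
    }, error = function(e) NULL)
    if (is.null(hc)) next
    for (side in c("left", "right")) {
      lab <- NA_character_
      if (!is.na(truth_id)) {
        sel <- ai$half_labels$box_id == truth_id & ai$half_labels$side == side
        if (any(sel)) lab <- ai$half_labels$label[sel][1]
      }
      if (labels_from_truth && is.na(lab)) next
      eh <- tryCatch(
        preprocess_half(hc[[side]], platform_row = 0,
                        tiles = cfg$enhance$tiles,
                        clip_limit = cfg$enhance$clip_limit),
        error = function(e) NULL)
      if (is.null(eh)) next
      halves[[length(halves) + 1]] <- list(pixels = eh$pixels, label = lab,
                                           side = side, box_id = truth_id)
    }
  }
  halves
}

#' Run the full pipeline on synthetic data
#'
#' Generates an annotated synthetic dataset, trains the detector on one
#' portion and detects on the held-out portion, crops and splits every
#' detection into enhanced halves, trains the classifier on truth-box
#' halves of the training portion, classifies the detected halves of the
#' held-out portion, and reports both confusion matrices with derived
#' metrics. Fully reproducible from (config, seed); any stage failure
#' aborts with the stage name.
#'
#' @param config A [validate_config()]-clean `pipeline_config`.
#' @param seed Optional override of `config$seed`.
#' @return A list of class `pipeline_report`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), seed = NULL) {
  cfg <- validate_config(config)
  if (inherits(cfg, "config_violations"))
    stop("run_pipeline: invalid configuration:\n",
         paste(" -", cfg, collapse = "\n"))
  seed <- seed %||% cfg$seed

  data <- stage("synth", {
    sspec <- synth_spec(
      image_width = cfg$synth$image_width, image_height = cfg$synth$image_height,
      n_implants = cfg$synth$n_implants, thread_pitch = cfg$synth$thread_pitch,
      shaft_width = cfg$synth$shaft_width, shaft_intensity = cfg$synth$shaft_intensity,
      background_mean = cfg$synth$background_mean,
      background_noise_sd = cfg$synth$background_noise_sd,
      defect_depth_threads = cfg$synth$defect_depth_threads,
      defect_darkening = cfg$synth$defect_darkening,
      rotation_max_deg = cfg$synth$rotation_max_deg, n_teeth = cfg$synth$n_teeth)
    generate_dataset(sspec, cfg$synth$n_images, cfg$synth$damaged_fraction, seed)
  })
  n_train <- max(1, round(cfg$detect$train_fraction * length(data)))
  train_imgs <- data[seq_len(n_train)]
  test_imgs <- data[setdiff(seq_along(data), seq_len(n_train))]

  detector <- stage("detect", {
    dcfg <- detector_config(
      input_size = cfg$detect$input_size, n_anchors = cfg$detect$n_anchors,
      conf_threshold = cfg$detect$conf_threshold, nms_iou = cfg$detect$nms_iou,
      initial_learning_rate = cfg$detect$initial_learning_rate,
      max_epoch = cfg$detect$max_epoch,
      mini_batch_size = cfg$detect$mini_batch_size,
      width_multiplier = cfg$detect$width_multiplier)
    train_detector(build_detector(dcfg), train_imgs, seed = seed)
  })
  detections <- stage("detect", lapply(test_imgs, function(ai)
    detect_implants(detector, ai$pixels)))
  det_cm <- stage("evaluate", evaluate_detection(
    detections, lapply(test_imgs, `[[`, "boxes"),
    lapply(test_imgs, `[[`, "tooth_boxes"), cfg$evaluate$iou_match))

  train_halves <- stage("crop", {
    h <- unlist(lapply(train_imgs, function(ai)
      image_to_halves(ai, ai$boxes, cfg)), recursive = FALSE)
    if (length(h) == 0) stop("no training halves produced")
    h
  })
  test_halves <- stage("crop", unlist(lapply(seq_along(test_imgs), function(i)
    image_to_halves(test_imgs[[i]], detections[[i]], cfg)), recursive = FALSE))

  classifier <- stage("classify", {
    ccfg <- classifier_config(
      input_height = cfg$classify$input_height, input_width = cfg$classify$input_width,
      initial_learning_rate = cfg$classify$initial_learning_rate,
      max_epoch = cfg$classify$max_epoch,
      mini_batch_size = cfg$classify$mini_batch_size,
      lr_drop_factor = cfg$classify$lr_drop_factor,
      lr_drop_period = cfg$classify$lr_drop_period,
      dropout_probability = cfg$classify$dropout_probability,
      width_multiplier = cfg$classify$width_multiplier)
    split <- make_split(train_halves, cfg$classify$train_fraction, seed = seed)
    train_classifier(build_classifier(ccfg), split, seed = seed)
  })

  cls_cm <- stage("classify", {
    if (length(test_halves) == 0) stop("no test halves to classify")
    pred <- vapply(test_halves, function(h) classify_half(classifier, h)$label,
                   character(1))
    truth <- vapply(test_halves, `[[`, character(1), "label")
    confusion_from_predictions(pred, truth, positive = "damaged")
  })

  report <- structure(list(
    seed = seed,
    n_images = length(data), n_test_images = length(test_imgs),
    detection = list(confusion = det_cm, metrics = matrix_metrics(det_cm)),
    classification = list(confusion = cls_cm, metrics = matrix_metrics(cls_cm),
                          n_halves = length(test_halves)),
    detector_loss = list(first = detector$loss_trace[1],
                         last = mean(utils::tail(detector$loss_trace,
                                                 max(1, length(detector$loss_trace) %/% 10)))),
    classifier_history = classifier$history
  ), class = "pipeline_report")

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    rep_json <- list(
      seed = seed, n_images = report$n_images,
      detection = c(as.list(det_cm)[c("tp", "fp", "fn", "tn")],
                    accuracy = report$detection$metrics$accuracy),
      classification = c(as.list(cls_cm)[c("tp", "fp", "fn", "tn")],
                         accuracy = report$classification$metrics$accuracy))
    jsonlite::write_json(rep_json, file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(classifier$history,
                     file.path(cfg$output_dir, "classifier_history.csv"),
                     row.names = FALSE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report seed %s: %d images (%d held out)>\n",
              format(x$seed), x$n_images, x$n_test_images))
  cat(sprintf("detection  : acc %.1f%%, recall %.1f%% (tp %d fp %d fn %d tn %d)\n",
              x$detection$metrics$accuracy, x$detection$metrics$recall_positive,
              x$detection$confusion$tp, x$detection$confusion$fp,
              x$detection$confusion$fn, x$detection$confusion$tn))
  cat(sprintf("classify   : acc %.1f%% on %d halves\n",
              x$classification$metrics$accuracy, x$classification$n_halves))
  invisible(x)
}
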