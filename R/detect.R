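#' Configuration of the implant-thread detector
#'
#' A single-class grid detector in the YOLOv2 mould: a fully-convolutional
#' backbone downsampling by 32, predicting per grid cell `n_anchors` boxes
#' with 5 values each (x, y, w, h offsets plus objectness) and one class
#' score, so the output depth is `n_anchors * (5 + n_classes)`; with one
#' class and five anchors that is the canonical 13 x 13 x 30 map for a
#' 416 x 416 input.
#'
#' @param input_size Square input side in pixels; must be divisible by 32.
#' @param n_anchors Number of anchor priors per cell.
#' @param anchors Optional `n_anchors` x 2 matrix of (w, h) priors in grid
#'   units; estimated from the training boxes by IoU k-means when `NULL`.
#' @param conf_threshold Detection confidence threshold in (0, 1).
#' @param nms_iou Non-maximum-suppression overlap threshold in (0, 1).
#' @param optimizer Only `"sgdm"` (stochastic gradient descent with
#'   momentum) is supported.
#' @param momentum Momentum coefficient of sgdm.
#' @param initial_learning_rate Learning rate.
#' @param max_epoch Training epochs.
#' @param mini_batch_size Mini-batch size; incomplete trailing batches are
#'   discarded.
#' @param n_classes Number of object classes (1: implant thread).
#' @param width_multiplier Scales every backbone channel width (the head
#'   depth is fixed by anchors and classes); 1 reproduces the reference
#'   architecture, fractions give a reduced detector for CPU-scale studies.
#' @return Object of class `detector_config`.
#' @export
detector_config <- function(input_size = 416, n_anchors = 5, anchors = NULL,
                            conf_threshold = 0.5, nms_iou = 0.5,
                            optimizer = "sgdm", momentum = 0.9,
                            initial_learning_rate = 0.001, max_epoch = 24,
                            mini_batch_size = 16, n_classes = 1,
                            width_multiplier = 1) {
  if (input_size %% 32 != 0)
    stop("detector_config: input_size must be divisible by 32 (the backbone downsamples by 32)")
  if (conf_threshold <= 0 || conf_threshold >= 1 || nms_iou <= 0 || nms_iou >= 1)
    stop("detector_config: conf_threshold and nms_iou must lie in (0, 1)")
  if (!identical(optimizer, "sgdm")) stop("detector_config: optimizer must be 'sgdm'")
  structure(list(
    input_size = as.integer(input_size), grid = as.integer(input_size / 32),
    n_anchors = as.integer(n_anchors), anchors = anchors,
    conf_threshold = conf_threshold, nms_iou = nms_iou,
    optimizer = optimizer, momentum = momentum,
    initial_learning_rate = initial_learning_rate,
    max_epoch = as.integer(max_epoch),
    mini_batch_size = as.integer(mini_batch_size),
    n_classes = as.integer(n_classes), width_multiplier = width_multiplier
  ), class = "detector_config")
}

detector_widths <- function(mult) {
  w <- round(c(16, 32, 64, 128, 256, 512, 1024, 512) * mult)
  pmax(w, 2L)
}

#' Build the detector model
#'
#' Assembles the backbone (seven 3x3 convolution blocks with batch
#' normalization and leaky ReLU, max-pooling down to the grid resolution,
#' the sixth pool at stride 1) and the 1x1 prediction head, and records the
#' full layer table with activation shapes. The model is untrained until
#' [train_detector()] attaches parameters.
#'
#' @param config A [detector_config()].
#' @return Object of class `detector_model` with elements `config`,
#'   `layers` (data frame of layer types and activation shapes), `spec`
#'   (internal network description), `params`, `anchors`.
#' @export
build_detector <- function(config = detector_config()) {
  stopifnot(inherits(config, "detector_config"))
  wd <- detector_widths(config$width_multiplier)
  depth <- config$n_anchors * (5 + config$n_classes)
  spec <- list(list(type = "input", h = config$input_size, w = config$input_size, c = 3L))
  add <- function(spec, ...) c(spec, list(list(...)))
  for (b in 1:5) {
    spec <- add(spec, type = "conv", out_c = wd[b], k = 3L, stride = 1L, pad = 1L)
    spec <- add(spec, type = "bn")
    spec <- add(spec, type = "lrelu", alpha = 0.1)
    spec <- add(spec, type = "maxpool", k = 2L, stride = 2L, pad = 0L)
  }
  spec <- add(spec, type = "conv", out_c = wd[6], k = 3L, stride = 1L, pad = 1L)
  spec <- add(spec, type = "bn")
  spec <- add(spec, type = "lrelu", alpha = 0.1)
  spec <- add(spec, type = "maxpool", k = 2L, stride = 1L, pad = 0L, pad_extra = 1L)
  spec <- add(spec, type = "conv", out_c = wd[7], k = 3L, stride = 1L, pad = 1L)
  spec <- add(spec, type = "bn")
  spec <- add(spec, type = "lrelu", alpha = 0.1)
  spec <- add(spec, type = "conv", out_c = wd[8], k = 3L, stride = 1L, pad = 1L)
  spec <- add(spec, type = "bn")
  spec <- add(spec, type = "lrelu", alpha = 0.1)
  spec <- add(spec, type = "conv", out_c = depth, k = 1L, stride = 1L, pad = 0L)

  sh <- cpp_nn_shapes(spec)$shapes
  type_names <- c(conv = "2-D Convolution", bn = "Batch Normalization",
                  lrelu = "Leaky ReLU", maxpool = "2-D Max Pooling")
  types <- vapply(spec[-1], function(l) type_names[[l$type]], character(1))
  act <- sprintf("%d × %d × %d", sh[, 1], sh[, 2], sh[, 3])
  layers <- data.frame(
    index = seq_len(length(types) + 3),
    type = c("Image Input", types, "Transform Layer", "Output"),
    activations = c(sprintf("%d × %d × %d", config$input_size, config$input_size, 3L),
                    act, act[length(act)], act[length(act)]),
    stringsAsFactors = FALSE)
  structure(list(config = config, layers = layers, spec = spec,
                 params = NULL, anchors = config$anchors, loss_trace = NULL),
            class = "detector_model")
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf("<detector_model %dx%d input, grid %d, %d anchors, %s>\n",
              x$config$input_size, x$config$input_size, x$config$grid,
              x$config$n_anchors,
              if (is.null(x$params)) "untrained" else "trained"))
  invisible(x)
}

#' Epoch/iteration arithmetic of mini-batch training
#'
#' One epoch is a full pass over the dataset in mini-batches:
#' `iterations_per_epoch = floor(dataset_size / batch_size)` (the incomplete
#' trailing batch is discarded) and
#' `total_iterations = iterations_per_epoch * max_epoch`.
#'
#' @param dataset_size,batch_size,max_epoch Counts (`batch_size >= 1`).
#' @return Object of class `training_schedule`.
#' @export
compute_schedule <- function(dataset_size, batch_size, max_epoch) {
  if (batch_size < 1) stop("compute_schedule: batch_size must be >= 1")
  if (dataset_size < batch_size)
    stop("compute_schedule: dataset smaller than one batch gives zero iterations")
  ipe <- dataset_size %/% batch_size
  structure(list(dataset_size = as.integer(dataset_size),
                 batch_size = as.integer(batch_size),
                 max_epoch = as.integer(max_epoch),
                 iterations_per_epoch = as.integer(ipe),
                 total_iterations = as.integer(ipe * max_epoch)),
            class = "training_schedule")
}

#' Intersection over union of two boxes
#'
#' @param a,b Boxes (`x, y, w, h` lists or one-row data frames).
#' @return IoU in `[0, 1]`.
#' @export
iou_box <- function(a, b) {
  ix <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  iy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  inter <- ix * iy
  un <- a$w * a$h + b$w * b$h - inter
  if (un <= 0) 0 else inter / un
}

## anchor estimation: Lloyd k-means under the 1 - IoU distance on (w, h)
estimate_anchors <- function(wh, k, seed = 1, iters = 50) {
  wh <- wh[wh[, 1] > 0 & wh[, 2] > 0, , drop = FALSE]
  if (nrow(wh) < k) {
    base <- wh[rep(seq_len(nrow(wh)), length.out = k), , drop = FALSE]
    return(base * matrix(seq(0.8, 1.2, length.out = k), k, 2))
  }
  iou_wh <- function(a, b) {
    inter <- pmin(a[1], b[, 1]) * pmin(a[2], b[, 2])
    inter / (a[1] * a[2] + b[, 1] * b[, 2] - inter)
  }
  with_local_seed(seed, {
    centers <- wh[sample.int(nrow(wh), k), , drop = FALSE]
    for (it in seq_len(iters)) {
      d <- sapply(seq_len(k), function(j) 1 - iou_wh(centers[j, ], wh))
      assign <- max.col(-d)
      newc <- t(sapply(seq_len(k), function(j) {
        sel <- assign == j
        if (any(sel)) colMeans(wh[sel, , drop = FALSE]) else centers[j, ]
      }))
      if (max(abs(newc - centers)) < 1e-9) { centers <- newc; break }
      centers <- newc
    }
    centers[order(centers[, 1] * centers[, 2]), , drop = FALSE]
  })
}

boxes_to_grid <- function(boxes, img_w, img_h, grid) {
  if (nrow(boxes) == 0) return(matrix(numeric(0), 0, 4))
  cbind(cx = (boxes$x + boxes$w / 2) * grid / img_w,
        cy = (boxes$y + boxes$h / 2) * grid / img_h,
        w = boxes$w * grid / img_w,
        h = boxes$h * grid / img_h)
}

detector_targets <- function(gb, anchors, grid) {
  if (nrow(gb) == 0)
    return(list(gt = matrix(numeric(0), 0, 7), boxes = matrix(numeric(0), 0, 4)))
  iou_wh <- function(a, b) {
    inter <- pmin(a[1], b[1]) * pmin(a[2], b[2])
    inter / (a[1] * a[2] + b[1] * b[2] - inter)
  }
  gt <- matrix(numeric(0), 0, 7)
  used <- character(0)
  for (r in seq_len(nrow(gb))) {
    cj <- min(max(floor(gb[r, 1]), 0), grid - 1)
    ci <- min(max(floor(gb[r, 2]), 0), grid - 1)
    a <- which.max(vapply(seq_len(nrow(anchors)),
                          function(j) iou_wh(gb[r, 3:4], anchors[j, ]), numeric(1))) - 1
    key <- paste(ci, cj, a)
    if (key %in% used) next
    used <- c(used, key)
    gt <- rbind(gt, c(ci, cj, a,
                      gb[r, 1] - cj, gb[r, 2] - ci,
                      log(gb[r, 3] / anchors[a + 1, 1]),
                      log(gb[r, 4] / anchors[a + 1, 2])))
  }
  list(gt = gt, boxes = gb)
}

image_to_input <- function(pixels, input_size) {
  g <- resize_image(as_gray8(pixels), input_size, input_size) / 255
  rep(as.vector(g), 3)
}

#' Train the implant-thread detector
#'
#' Trains with the multi-part grid-detection loss (coordinate, objectness
#' and no-object terms with the conventional 5 / 1 / 0.5 weights) under SGD
#' with momentum. No validation split is consumed; the full dataset is used
#' for training and the per-iteration loss is the only trace, matching the
#' reference training protocol. Anchors are taken from the config or
#' estimated from the training boxes by IoU k-means.
#'
#' @param model A [build_detector()] result.
#' @param data List of `annotated_image` objects (boxes may be empty).
#' @param config Optional override of `model$config`.
#' @param seed Seed for weight initialization and batch shuffling.
#' @return The model with `params`, `anchors` and `loss_trace` (length =
#'   `total_iterations` from [compute_schedule()]).
#' @export
train_detector <- function(model, data, config = model$config, seed = 1) {
  stopifnot(inherits(model, "detector_model"))
  if (length(data) == 0) stop("train_detector: empty dataset")
  S <- config$grid
  X <- vapply(data, function(ai) image_to_input(ai$pixels, config$input_size),
              numeric(config$input_size^2 * 3))
  gbs <- lapply(data, function(ai)
    boxes_to_grid(ai$boxes, ncol(ai$pixels), nrow(ai$pixels), S))
  anchors <- model$anchors %||% config$anchors
  if (is.null(anchors)) {
    allwh <- do.call(rbind, lapply(gbs, function(g) g[, 3:4, drop = FALSE]))
    if (is.null(allwh) || nrow(allwh) == 0)
      anchors <- cbind(w = seq(0.5, 2.5, length.out = config$n_anchors),
                       h = seq(1, 5, length.out = config$n_anchors))
    else anchors <- estimate_anchors(allwh, config$n_anchors, seed = seed)
  }
  tg <- lapply(gbs, detector_targets, anchors = anchors, grid = S)
  sched <- compute_schedule(length(data), config$mini_batch_size, config$max_epoch)
  params <- cpp_nn_init(model$spec, seed)
  fit <- cpp_nn_train_yolo(model$spec, params, X,
                           lapply(tg, `[[`, "gt"), lapply(tg, `[[`, "boxes"),
                           anchors, config$n_classes,
                           sched$max_epoch, sched$batch_size,
                           config$initial_learning_rate, config$momentum,
                           seed)
  model$params <- fit$params
  model$anchors <- anchors
  model$loss_trace <- fit$loss_trace
  model$config <- config
  model
}

#' Detect implant threads in a radiograph
#'
#' Runs the trained detector, decodes the grid predictions into pixel boxes,
#' keeps those at or above the confidence threshold, and (by default)
#' applies greedy non-maximum suppression; without suppression the detector
#' reproduces the known duplicate-detection behaviour on partially visible
#' implants.
#'
#' @param model Trained [detector_model].
#' @param image Grayscale matrix (or `annotated_image`); at least 32 x 32.
#' @param conf_threshold,nms_iou Optional overrides of the config values.
#' @param apply_nms Set `FALSE` to disable suppression.
#' @return Data frame `x, y, w, h, confidence, class_name`, sorted by
#'   descending confidence, coordinates in the input image's pixels.
#' @export
detect_implants <- function(model, image, conf_threshold = NULL, nms_iou = NULL,
                            apply_nms = TRUE) {
  stopifnot(inherits(model, "detector_model"))
  if (is.null(model$params)) stop("detect_implants: model is untrained")
  px <- if (inherits(image, "annotated_image")) image$pixels else image
  if (nrow(px) < 32 || ncol(px) < 32)
    stop("detect_implants: image must be at least 32 x 32 pixels")
  cfg <- model$config
  conf_threshold <- conf_threshold %||% cfg$conf_threshold
  nms_iou <- nms_iou %||% cfg$nms_iou
  S <- cfg$grid; A <- cfg$n_anchors; Fd <- 5 + cfg$n_classes
  out <- cpp_nn_forward(model$spec, model$params,
                        matrix(image_to_input(px, cfg$input_size), ncol = 1))
  o <- array(out[, 1], dim = c(S, S, A * Fd))
  sigm <- function(x) 1 / (1 + exp(-x))
  cellw <- ncol(px) / S; cellh <- nrow(px) / S
  dets <- list()
  for (a in seq_len(A)) {
    base <- (a - 1) * Fd
    conf <- sigm(o[, , base + 5])
    sel <- which(conf >= conf_threshold, arr.ind = TRUE)
    if (nrow(sel) == 0) next
    for (r in seq_len(nrow(sel))) {
      ci <- sel[r, 1]; cj <- sel[r, 2]
      bx <- (cj - 1) + sigm(o[ci, cj, base + 1])
      by <- (ci - 1) + sigm(o[ci, cj, base + 2])
      bw <- model$anchors[a, 1] * exp(o[ci, cj, base + 3])
      bh <- model$anchors[a, 2] * exp(o[ci, cj, base + 4])
      dets[[length(dets) + 1]] <- data.frame(
        x = (bx - bw / 2) * cellw, y = (by - bh / 2) * cellh,
        w = bw * cellw, h = bh * cellh,
        confidence = conf[ci, cj], class_name = "implant")
    }
  }
  if (length(dets) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                      h = numeric(0), confidence = numeric(0),
                      class_name = character(0)))
  df <- do.call(rbind, dets)
  df <- df[order(-df$confidence), , drop = FALSE]
  rownames(df) <- NULL
  if (apply_nms) nms_boxes(df, nms_iou) else df
}

#' Greedy non-maximum suppression
#'
#' Keeps detections in order of descending confidence, discarding any box
#' whose IoU with an already-kept box is at least `iou`. Idempotent.
#'
#' @param boxes Data frame with `x, y, w, h, confidence`.
#' @param iou Suppression threshold.
#' @return The surviving subset, still sorted by descending confidence.
#' @export
nms_boxes <- function(boxes, iou = 0.5) {
  if (nrow(boxes) <= 1) return(boxes)
  boxes <- boxes[order(-boxes$confidence), , drop = FALSE]
  keep <- logical(nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (iou_box(boxes[i, ], boxes[j, ]) >= iou) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  out <- boxes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate detections against implant and tooth ground truth
#'
#' Predictions are matched one-to-one to implant truths greedily by
#' descending confidence at `IoU >= iou_match`: matched truths are TP,
#' unmatched truths FN. Remaining predictions are FP (whether they fall on
#' a tooth region or on nothing), and tooth regions never claimed by a
#' prediction are TN -- teeth act as the negative class of the detection
#' confusion matrix.
#'
#' @param predictions Per-image list of prediction data frames.
#' @param truth_implants Per-image list of implant truth boxes.
#' @param truth_teeth Per-image list of tooth boxes (may be `NULL`).
#' @param iou_match Matching threshold in (0, 1).
#' @return A [confusion_matrix()] with classes Implant / Tooth.
#' @export
evaluate_detection <- function(predictions, truth_implants, truth_teeth = NULL,
                               iou_match = 0.5) {
  if (iou_match <= 0 || iou_match >= 1)
    stop("evaluate_detection: iou_match must lie in (0, 1)")
  n <- length(predictions)
  if (length(truth_implants) != n ||
      (!is.null(truth_teeth) && length(truth_teeth) != n))
    stop("evaluate_detection: inputs must cover the same images")
  if (!is.null(names(predictions)) && !is.null(names(truth_implants)) &&
      !identical(sort(names(predictions)), sort(names(truth_implants))))
    stop("evaluate_detection: image keys differ between predictions and truth")
  if (!is.null(names(predictions)) && !is.null(names(truth_implants)))
    truth_implants <- truth_implants[names(predictions)]
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(n)) {
    preds <- predictions[[i]]
    truths <- truth_implants[[i]]
    teeth <- if (is.null(truth_teeth)) NULL else truth_teeth[[i]]
    n_tr <- if (is.null(truths)) 0 else nrow(truths)
    n_pr <- if (is.null(preds)) 0 else nrow(preds)
    matched_t <- rep(FALSE, n_tr)
    matched_p <- rep(FALSE, n_pr)
    if (n_pr > 0 && !is.null(preds$confidence))
      preds <- preds[order(-preds$confidence), , drop = FALSE]
    for (p in seq_len(n_pr)) {
      best <- 0; bt <- 0
      for (t in seq_len(n_tr)) {
        if (matched_t[t]) next
        ov <- iou_box(preds[p, ], truths[t, ])
        if (ov > best) { best <- ov; bt <- t }
      }
      if (bt > 0 && best >= iou_match) { matched_t[bt] <- TRUE; matched_p[p] <- TRUE }
    }
    tp <- tp + sum(matched_t)
    fn <- fn + sum(!matched_t)
    fp <- fp + sum(!matched_p)
    if (!is.null(teeth) && nrow(teeth) > 0) {
      claimed <- rep(FALSE, nrow(teeth))
      for (p in which(!matched_p)) {
        for (t in seq_len(nrow(teeth))) {
          if (!claimed[t] && iou_box(preds[p, ], teeth[t, ]) >= iou_match) {
            claimed[t] <- TRUE; break
          }
        }
      }
      tn <- tn + sum(!claimed)
    }
  }
  confusion_matrix(tp, fp, fn, tn,
                   positive_name = "Implant", negative_name = "Tooth")
}
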