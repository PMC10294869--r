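#' Configuration of the damaged/healthy half-image classifier
#'
#' An AlexNet-style network with a tall 450 x 250 x 3 input frame suited to
#' the elongated shape of implant halves (a square frame would force either
#' distortion or excessive padding), trained with SGD-momentum under a
#' stepped learning-rate schedule.
#'
#' @param input_height,input_width Input frame in pixels.
#' @param channels Input channels (3: the enhanced halves are color-coded).
#' @param n_classes Output classes (2: damaged / healthy).
#' @param optimizer Only `"sgdm"` is supported.
#' @param momentum Momentum coefficient.
#' @param initial_learning_rate Starting learning rate.
#' @param max_epoch Training epochs (50 default; longer runs only refine).
#' @param mini_batch_size Mini-batch size.
#' @param lr_drop_factor Multiplicative learning-rate drop in (0, 1].
#' @param lr_drop_period Epochs between drops.
#' @param dropout_probability Dropout probability at both dropout layers.
#' @param width_multiplier Scales convolution and hidden FC widths; 1
#'   reproduces the reference architecture.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(input_height = 450, input_width = 250,
                              channels = 3, n_classes = 2,
                              optimizer = "sgdm", momentum = 0.9,
                              initial_learning_rate = 6e-5, max_epoch = 50,
                              mini_batch_size = 16, lr_drop_factor = 0.75,
                              lr_drop_period = 30, dropout_probability = 0.5,
                              width_multiplier = 1) {
  if (lr_drop_factor <= 0 || lr_drop_factor > 1)
    stop("classifier_config: lr_drop_factor must be in (0, 1]")
  if (any(c(input_height, input_width, channels, n_classes, max_epoch,
            mini_batch_size, lr_drop_period) < 1) || initial_learning_rate <= 0)
    stop("classifier_config: all sizes and rates must be positive")
  structure(list(
    input_height = as.integer(input_height), input_width = as.integer(input_width),
    channels = as.integer(channels), n_classes = as.integer(n_classes),
    optimizer = optimizer, momentum = momentum,
    initial_learning_rate = initial_learning_rate,
    max_epoch = as.integer(max_epoch), mini_batch_size = as.integer(mini_batch_size),
    lr_drop_factor = lr_drop_factor, lr_drop_period = as.integer(lr_drop_period),
    dropout_probability = dropout_probability, width_multiplier = width_multiplier
  ), class = "classifier_config")
}

even <- function(x) as.integer(pmax(2, 2 * round(x / 2)))

#' Build the half-image classifier
#'
#' Layer sequence: 11x11/4 convolution, ReLU, cross-channel normalization,
#' 3x3/2 max pool; 5x5 grouped convolution (2 groups), ReLU, normalization,
#' pool; three 3x3 convolutions (the middle two grouped); pool; then three
#' fully-connected stages (1152, 144, `n_classes`) with dropout between
#' them, ending in softmax.
#'
#' @param config A [classifier_config()].
#' @return Object of class `classifier_model` with `config`, `layers`
#'   (activation-shape table), `spec`, `params`, `history`.
#' @export
build_classifier <- function(config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  m <- config$width_multiplier
  cw <- c(even(96 * m), even(256 * m), even(384 * m), even(384 * m), even(256 * m))
  fw <- c(max(4L, round(1152 * m)), max(4L, round(144 * m)))
  p <- config$dropout_probability
  spec <- list(
    list(type = "input", h = config$input_height, w = config$input_width, c = config$channels),
    list(type = "conv", out_c = cw[1], k = 11L, stride = 4L, pad = 0L),
    list(type = "relu"),
    list(type = "lrn", window = 5L, alpha = 1e-4, beta = 0.75, k = 2),
    list(type = "maxpool", k = 3L, stride = 2L, pad = 0L),
    list(type = "conv", out_c = cw[2], k = 5L, stride = 1L, pad = 2L, groups = 2L),
    list(type = "relu"),
    list(type = "lrn", window = 5L, alpha = 1e-4, beta = 0.75, k = 2),
    list(type = "maxpool", k = 3L, stride = 2L, pad = 0L),
    list(type = "conv", out_c = cw[3], k = 3L, stride = 1L, pad = 1L),
    list(type = "relu"),
    list(type = "conv", out_c = cw[4], k = 3L, stride = 1L, pad = 1L, groups = 2L),
    list(type = "relu"),
    list(type = "conv", out_c = cw[5], k = 3L, stride = 1L, pad = 1L, groups = 2L),
    list(type = "relu"),
    list(type = "maxpool", k = 3L, stride = 2L, pad = 0L),
    list(type = "fc", out = fw[1]),
    list(type = "relu"),
    list(type = "dropout", p = p),
    list(type = "fc", out = fw[2]),
    list(type = "relu"),
    list(type = "dropout", p = p),
    list(type = "fc", out = config$n_classes)
  )
  sh <- cpp_nn_shapes(spec)$shapes
  if (any(sh[, 1:2] < 1))
    stop("build_classifier: input too small for the stride chain")
  type_names <- c(conv = "2-D Convolution", relu = "ReLU",
                  lrn = "Cross Channel Normalization",
                  maxpool = "2-D Max Pooling", fc = "Fully Connected",
                  dropout = "Dropout")
  types <- vapply(spec[-1], function(l) {
    if (l$type == "conv" && !is.null(l$groups) && l$groups > 1) "2-D Grouped Convolution"
    else type_names[[l$type]]
  }, character(1))
  act <- sprintf("%d × %d × %d", sh[, 1], sh[, 2], sh[, 3])
  nl <- length(types)
  layers <- data.frame(
    index = seq_len(nl + 3),
    type = c("Image Input", types, "Softmax", "Classification Output"),
    activations = c(sprintf("%d × %d × %d", config$input_height,
                            config$input_width, config$channels),
                    act, act[nl], act[nl]),
    stringsAsFactors = FALSE)
  structure(list(config = config, layers = layers, spec = spec,
                 params = NULL, history = NULL,
                 class_levels = c("damaged", "healthy")),
            class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf("<classifier_model %dx%dx%d input, %d classes, %s>\n",
              x$config$input_height, x$config$input_width, x$config$channels,
              x$config$n_classes,
              if (is.null(x$params)) "untrained" else "trained"))
  invisible(x)
}

#' Quadruple a labeled image set by flips
#'
#' Each image yields its original, horizontal flip, vertical flip, and
#' combined flip, all inheriting the source label, so the output holds
#' exactly four times the input count (variants of symmetric images are
#' emitted even when pixel-identical).
#'
#' @param images List of records `list(pixels, label)`; `pixels` a matrix
#'   or h x w x 3 array.
#' @return List of 4x as many records, variants of each input consecutive.
#' @export
augment_flips <- function(images) {
  if (length(images) == 0) stop("augment_flips: empty input")
  flip <- function(px, h, v) {
    if (length(dim(px)) == 3) {
      if (h) px <- px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
      if (v) px <- px[rev(seq_len(dim(px)[1])), , , drop = FALSE]
    } else {
      if (h) px <- px[, rev(seq_len(ncol(px))), drop = FALSE]
      if (v) px <- px[rev(seq_len(nrow(px))), , drop = FALSE]
    }
    px
  }
  out <- vector("list", 4 * length(images))
  k <- 0
  for (im in images) {
    for (fl in list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))) {
      k <- k + 1
      out[[k]] <- list(pixels = flip(im$pixels, fl[1], fl[2]), label = im$label)
    }
  }
  out
}

#' Stratified train/validation split with class balancing
#'
#' The majority class is down-sampled to the minority count (so the
#' damaged:healthy ratio is 1:1 up to one image), then each class is split
#' `train_fraction` / `1 - train_fraction`, and flip augmentation is
#' applied to the training portion only -- the validation set never
#' contains a flip-variant of any training image.
#'
#' @param images List of records `list(pixels, label)` with binary labels.
#' @param train_fraction Fraction in (0, 1]; 1 leaves validation empty
#'   (with a warning).
#' @param seed Seed controlling down-sampling and membership.
#' @param augment Apply [augment_flips()] to the training set?
#' @return Object of class `dataset_split`: `train`, `validation`,
#'   `train_fraction`, `class_counts`.
#' @export
make_split <- function(images, train_fraction = 0.8, seed = 1, augment = TRUE) {
  labels <- vapply(images, function(im) as.character(im$label), character(1))
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("make_split: both classes must be present")
  if (train_fraction <= 0 || train_fraction > 1)
    stop("make_split: train_fraction must be in (0, 1]")
  with_local_seed(seed, {
    nmin <- min(table(labels))
    keep <- unlist(lapply(classes, function(cl) {
      idx <- which(labels == cl)
      if (length(idx) > nmin) sort(sample(idx, nmin)) else idx
    }))
    train_idx <- unlist(lapply(classes, function(cl) {
      idx <- intersect(keep, which(labels == cl))
      sort(sample(idx, round(train_fraction * length(idx))))
    }))
    val_idx <- setdiff(keep, train_idx)
    if (length(val_idx) == 0) warning("make_split: validation set is empty")
    train <- images[train_idx]
    if (augment && length(train) > 0) train <- augment_flips(train)
    counts <- function(set) table(factor(vapply(set, function(im) as.character(im$label),
                                                character(1)), levels = classes))
    structure(list(train = train, validation = images[val_idx],
                   train_fraction = train_fraction,
                   class_counts = list(train = counts(train),
                                       validation = counts(images[val_idx]))),
              class = "dataset_split")
  })
}

#' Stepped learning-rate schedule
#'
#' `rate = initial * factor^floor((epoch - 1) / period)`: piecewise
#' constant, dropping by `lr_drop_factor` every `lr_drop_period` epochs.
#' Non-increasing in the epoch.
#'
#' @param epoch Epoch number (1-based) or vector of epochs.
#' @param config A [classifier_config()].
#' @return Learning rate(s).
#' @export
learning_rate_at <- function(epoch, config) {
  stopifnot(all(epoch >= 1))
  config$initial_learning_rate *
    config$lr_drop_factor^floor((epoch - 1) / config$lr_drop_period)
}

#' Prepare one half-image for the classifier input frame
#'
#' Aspect-preserving resize with symmetric zero padding (see
#' [resize_pad()]), channel replication for grayscale inputs, and scaling
#' to `[0, 1]`.
#'
#' @param pixels `enhanced_half`, `half_crop`, matrix or array.
#' @param config A [classifier_config()].
#' @return Numeric vector of length `height * width * channels`.
#' @export
prepare_classifier_input <- function(pixels, config) {
  if (is.list(pixels)) pixels <- pixels$pixels
  px <- to_rgb(pixels)
  as.vector(resize_pad(px, config$input_height, config$input_width)) / 255
}

split_to_matrices <- function(split, config, levels) {
  enc <- function(set) {
    if (length(set) == 0)
      return(list(X = matrix(0, config$input_height * config$input_width * config$channels, 0),
                  y = integer(0)))
    X <- vapply(set, prepare_classifier_input, config = config,
                numeric(config$input_height * config$input_width * config$channels))
    y <- match(vapply(set, function(im) as.character(im$label), character(1)), levels)
    if (anyNA(y)) stop("unknown class label in split")
    list(X = X, y = as.integer(y))
  }
  list(train = enc(split$train), validation = enc(split$validation))
}

#' Train the half-image classifier
#'
#' Softmax cross-entropy under SGD-momentum with the stepped
#' [learning_rate_at()] schedule; dropout is active in training passes
#' only. Per-epoch history records the running training loss/accuracy and
#' the validation metrics computed in inference mode.
#'
#' @param model A [build_classifier()] result.
#' @param split A [make_split()] result.
#' @param config Optional override of `model$config`.
#' @param seed Seed for weight initialization, shuffling and dropout.
#' @return The model with `params` and `history` (data frame: epoch, lr,
#'   train_loss, train_acc, val_loss, val_acc).
#' @export
train_classifier <- function(model, split, config = model$config, seed = 1) {
  stopifnot(inherits(model, "classifier_model"), inherits(split, "dataset_split"))
  if (length(split$train) == 0) stop("train_classifier: empty training set")
  enc <- split_to_matrices(split, config, model$class_levels)
  lr <- learning_rate_at(seq_len(config$max_epoch), config)
  params <- cpp_nn_init(model$spec, seed)
  fit <- cpp_nn_train_softmax(model$spec, params, enc$train$X, enc$train$y,
                              enc$validation$X, enc$validation$y,
                              config$max_epoch, config$mini_batch_size,
                              lr, config$momentum, seed)
  model$params <- fit$params
  model$history <- data.frame(epoch = seq_len(config$max_epoch),
                              lr = fit$history[, 1],
                              train_loss = fit$history[, 2],
                              train_acc = fit$history[, 3],
                              val_loss = fit$history[, 4],
                              val_acc = fit$history[, 5])
  model$config <- config
  model
}

#' Classify one enhanced half-image
#'
#' @param model Trained [classifier_model].
#' @param half `enhanced_half`, `half_crop`, matrix or array.
#' @return List with `label` (`"damaged"`/`"healthy"`), `probability` (of
#'   the reported label, in `[0.5, 1]` for two balanced classes), and the
#'   full softmax vector `probs`.
#' @export
classify_half <- function(model, half) {
  stopifnot(inherits(model, "classifier_model"))
  if (is.null(model$params)) stop("classify_half: model is untrained")
  x <- matrix(prepare_classifier_input(half, model$config), ncol = 1)
  logits <- cpp_nn_forward(model$spec, model$params, x)[, 1]
  p <- exp(logits - max(logits)); p <- p / sum(p)
  i <- which.max(p)
  list(label = model$class_levels[i], probability = p[i],
       probs = stats::setNames(p, model$class_levels))
}
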