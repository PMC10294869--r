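toy_images <- function(n, label, seed = 1, size = 8) {
  with_seed_imgs <- function() lapply(seq_len(n), function(i)
    list(pixels = matrix(sample(0:255, size * size, TRUE), size, size),
         label = label))
  set.seed(seed)
  with_seed_imgs()
}

test_that("flip augmentation exactly quadruples and preserves labels", {
  imgs <- c(toy_images(3, "healthy"), toy_images(2, "damaged", seed = 2))
  aug <- augment_flips(imgs)
  expect_length(aug, 20)
  expect_equal(sum(vapply(aug, `[[`, character(1), "label") == "healthy"), 12)

  # group structure: h-flip twice is the identity; variants of a symmetric
  # image coincide pixel-wise but are still emitted
  px <- imgs[[1]]$pixels
  hf <- aug[[2]]$pixels
  expect_identical(hf[, rev(seq_len(ncol(hf)))], px)
  sym <- list(list(pixels = matrix(5, 4, 4), label = "healthy"))
  aug_sym <- augment_flips(sym)
  expect_length(aug_sym, 4)
  expect_identical(aug_sym[[1]]$pixels, aug_sym[[4]]$pixels)
})

test_that("augmentation reproduces the reference training counts", {
  healthy <- toy_images(162, "healthy", size = 4)
  damaged <- toy_images(164, "damaged", size = 4)
  expect_length(augment_flips(healthy), 648)
  expect_length(augment_flips(damaged), 656)
})

test_that("the split is stratified, balanced, augmented on train only", {
  imgs <- c(toy_images(202, "healthy", size = 4),
            toy_images(204, "damaged", seed = 2, size = 4))
  sp <- make_split(imgs, 0.8, seed = 1)
  val_labs <- vapply(sp$validation, `[[`, character(1), "label")
  expect_equal(unname(table(val_labs)["healthy"]), 40, ignore_attr = TRUE)
  expect_equal(unname(table(val_labs)["damaged"]), 40, ignore_attr = TRUE)
  # train was balanced to 162 per class before the x4 augmentation
  expect_length(sp$train, 2 * 162 * 4)
  tr_labs <- vapply(sp$train, `[[`, character(1), "label")
  expect_equal(sum(tr_labs == "healthy"), sum(tr_labs == "damaged"))

  sp2 <- make_split(imgs, 0.8, seed = 1)
  expect_identical(vapply(sp2$validation, `[[`, character(1), "label"), val_labs)

  expect_warning(make_split(imgs, 1, seed = 1), "empty")
  expect_error(make_split(toy_images(5, "healthy"), 0.8), "both classes")
})

test_that("no flip-variant of a training image leaks into validation", {
  imgs <- c(toy_images(10, "healthy", seed = 3), toy_images(10, "damaged", seed = 4))
  sp <- make_split(imgs, 0.8, seed = 5)
  canon <- function(px) {
    variants <- list(px, px[, rev(seq_len(ncol(px)))],
                     px[rev(seq_len(nrow(px))), ],
                     px[rev(seq_len(nrow(px))), rev(seq_len(ncol(px)))])
    min(vapply(variants, function(v) paste(v, collapse = ","), character(1)))
  }
  tr <- vapply(sp$train, function(im) canon(im$pixels), character(1))
  va <- vapply(sp$validation, function(im) canon(im$pixels), character(1))
  expect_length(intersect(tr, va), 0)
})

test_that("the built classifier has the reference layer structure", {
  m <- build_classifier(classifier_config())
  expect_equal(nrow(m$layers), 25)
  expect_equal(m$layers$activations[2], "110 × 60 × 96")
  expect_equal(m$layers$activations[17], "1 × 1 × 1152")
  expect_equal(m$layers$activations[20], "1 × 1 × 144")
  expect_equal(m$layers$activations[23], "1 × 1 × 2")
  m3 <- build_classifier(classifier_config(n_classes = 3))
  expect_equal(m3$layers$activations[23], "1 × 1 × 3")
  expect_equal(m3$layers$activations[20], "1 × 1 × 144")
  expect_error(build_classifier(classifier_config(input_height = 40, input_width = 40)),
               "too small")
})

test_that("the stepped learning-rate schedule drops by the factor each period", {
  cfg <- classifier_config()
  expect_equal(learning_rate_at(1, cfg), 6e-5)
  expect_equal(learning_rate_at(30, cfg), 6e-5)
  expect_equal(learning_rate_at(31, cfg), 4.5e-5)
  expect_equal(learning_rate_at(61, cfg), 3.375e-5)
  lr <- learning_rate_at(1:100, cfg)
  expect_true(all(diff(lr) <= 0))
  expect_equal(which(diff(lr) < 0), c(30, 60, 90))
})

test_that("a tiny classifier trains, predicts normalized probabilities, and logs its schedule", {
  set.seed(1)
  mk <- function(n, label, bright) lapply(seq_len(n), function(i)
    list(pixels = matrix(pmin(255, pmax(0, rnorm(80 * 80, bright, 20))), 80, 80),
         label = label))
  imgs <- c(mk(12, "damaged", 40), mk(12, "healthy", 210))
  cfg <- classifier_config(input_height = 80, input_width = 80,
                           initial_learning_rate = 0.005, max_epoch = 6,
                           mini_batch_size = 4, width_multiplier = 0.125,
                           lr_drop_period = 3, lr_drop_factor = 0.5)
  model <- build_classifier(cfg)
  sp <- make_split(imgs, 0.75, seed = 2)
  fit <- train_classifier(model, sp, seed = 3)
  expect_equal(nrow(fit$history), 6)
  expect_equal(fit$history$lr, learning_rate_at(1:6, cfg))
  # brightness-separable classes are learned quickly
  expect_gte(utils::tail(fit$history$train_acc, 1), 0.9)

  pred <- classify_half(fit, imgs[[1]]$pixels)
  expect_equal(sum(pred$probs), 1, tolerance = 1e-12)
  expect_gte(pred$probability, 0.5)
  expect_true(pred$label %in% c("damaged", "healthy"))
  # determinism of training
  fit2 <- train_classifier(model, sp, seed = 3)
  expect_identical(fit$history, fit2$history)

  expect_error(classify_half(model, imgs[[1]]$pixels), "untrained")
})
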