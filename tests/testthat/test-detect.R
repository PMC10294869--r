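test_that("detector config enforces the grid and threshold invariants", {
  cfg <- detector_config()
  expect_equal(cfg$grid, 13)
  expect_equal(cfg$n_anchors * (5 + cfg$n_classes), 30)
  expect_error(detector_config(input_size = 208), "divisible by 32")
  expect_error(detector_config(conf_threshold = 1.2), "conf_threshold")
})

test_that("schedule arithmetic discards incomplete trailing batches", {
  s <- compute_schedule(10, 2, 1)
  expect_equal(s$iterations_per_epoch, 5)
  expect_equal(s$total_iterations, 5)
  expect_equal(compute_schedule(147, 16, 24)$total_iterations, 216)
  s3 <- compute_schedule(16, 16, 3)
  expect_equal(s3$iterations_per_epoch, 1)
  expect_equal(s3$total_iterations, 3)
  expect_error(compute_schedule(10, 16, 1), "zero iterations")
  # conservation property
  for (n in c(31, 100, 147)) for (b in c(4, 16)) {
    s <- compute_schedule(n, b, 7)
    expect_equal(s$total_iterations, (n %/% b) * 7)
  }
})

test_that("the built detector has the reference layer structure", {
  m <- build_detector(detector_config())
  expect_equal(nrow(m$layers), 34)
  expect_equal(m$layers$activations[2], "416 × 416 × 16")
  expect_equal(m$layers$activations[34], "13 × 13 × 30")
  expect_equal(m$layers$type[33], "Transform Layer")
  # reduced width keeps the head depth and grid
  r <- build_detector(detector_config(input_size = 160, width_multiplier = 0.125))
  expect_equal(r$layers$activations[34], "5 × 5 × 30")
})

test_that("IoU and greedy NMS behave as defined", {
  a <- list(x = 0, y = 0, w = 10, h = 10)
  expect_equal(iou_box(a, a), 1)
  expect_equal(iou_box(a, list(x = 20, y = 20, w = 5, h = 5)), 0)
  expect_equal(iou_box(a, list(x = 5, y = 0, w = 10, h = 10)), 50 / 150)

  # two candidates on one implant: the lower-confidence one is suppressed
  b <- data.frame(x = c(0, 1), y = c(0, 0), w = c(20, 20), h = c(40, 40),
                  confidence = c(0.9, 0.8))
  expect_equal(nrow(nms_boxes(b, 0.5)), 1)
  expect_equal(nms_boxes(b, 0.5)$confidence, 0.9)

  # idempotence on random boxes
  set.seed(1)
  for (i in 1:10) {
    bx <- random_boxes(12)
    once <- nms_boxes(bx, 0.4)
    expect_identical(nms_boxes(once, 0.4), once)
  }
})

test_that("detection evaluation counts TP/FP/FN/TN by one-to-one matching", {
  t1 <- data.frame(x = c(10, 100), y = c(10, 50), w = c(30, 30), h = c(60, 60))
  perfect <- cbind(t1, confidence = c(0.9, 0.8))
  cm <- evaluate_detection(list(perfect), list(t1), NULL, 0.5)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(2, 0, 0, 0))
  expect_equal(matrix_metrics(cm)$accuracy, 100)

  none <- data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                     h = numeric(0), confidence = numeric(0))
  t3 <- data.frame(x = c(0, 50, 100), y = 0, w = 20, h = 20)
  cm2 <- evaluate_detection(list(none), list(t3), NULL, 0.5)
  expect_equal(c(cm2$tp, cm2$fn), c(0, 3))

  # a stray detection on a tooth is FP; unclaimed teeth are TN
  teeth <- data.frame(x = 150, y = 10, w = 30, h = 60)
  stray <- data.frame(x = 151, y = 11, w = 30, h = 60, confidence = 0.7)
  cm3 <- evaluate_detection(list(rbind(perfect, stray)), list(t1), list(teeth), 0.5)
  expect_equal(c(cm3$tp, cm3$fp, cm3$tn), c(2, 1, 0))
  cm4 <- evaluate_detection(list(perfect), list(t1), list(teeth), 0.5)
  expect_equal(cm4$tn, 1)

  expect_error(evaluate_detection(list(perfect), list(t1), NULL, 1.5), "iou_match")
  expect_error(evaluate_detection(list(perfect), list(t1, t1)), "same images")
})

test_that("matching is one-to-one on random instances", {
  set.seed(9)
  for (i in 1:10) {
    preds <- random_boxes(sample(0:8, 1))
    truths <- random_boxes(sample(0:6, 1))[, 1:4]
    teeth <- random_boxes(sample(0:4, 1))[, 1:4]
    cm <- evaluate_detection(list(preds), list(truths), list(teeth), 0.3)
    expect_equal(cm$tp + cm$fn, nrow(truths))
    expect_equal(cm$tp + cm$fp, nrow(preds))
    expect_lte(cm$tn, nrow(teeth))
  }
})

test_that("anchor estimation returns the requested number of sane priors", {
  set.seed(2)
  wh <- cbind(runif(40, 0.5, 1.5), runif(40, 2, 4))
  a <- periapex:::estimate_anchors(wh, 5, seed = 1)
  expect_equal(dim(a), c(5, 2))
  expect_true(all(a > 0))
  expect_true(all(diff(a[, 1] * a[, 2]) >= 0))   # sorted by area
  # determinism
  expect_identical(a, periapex:::estimate_anchors(wh, 5, seed = 1))
})
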