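test_that("spec invariants are enforced", {
  expect_error(synth_spec(image_width = 100), "128")
  expect_error(synth_spec(shaft_intensity = 80, background_mean = 90), "exceed")
  expect_error(synth_spec(defect_present = TRUE, defect_depth_threads = 0),
               "defect_depth_threads")
  expect_error(synth_spec(defect_sides = list("up")), "defect_sides")
})

test_that("zero implants give an all-background image with empty annotations", {
  ai <- generate_radiograph(small_spec(n_implants = 0, n_teeth = 0))
  expect_equal(nrow(ai$boxes), 0)
  expect_equal(nrow(ai$half_labels), 0)
  # pure noise around the background mean, nothing bright
  expect_lt(mean(ai$pixels), 110)
  expect_lt(max(ai$pixels), 200)
})

test_that("identical spec and seed reproduce the image bit for bit", {
  s <- small_spec(seed = 7, defect_present = TRUE)
  a <- generate_radiograph(s)
  b <- generate_radiograph(s)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$boxes, b$boxes)
  expect_identical(a$half_labels, b$half_labels)
})

test_that("implants render brighter than background and boxes stay inside", {
  for (seed in 1:5) {
    ai <- generate_radiograph(small_spec(seed = seed, n_implants = 2,
                                         n_teeth = 0))
    W <- ncol(ai$pixels); H <- nrow(ai$pixels)
    shaft_any <- Reduce(`|`, ai$masks$shaft)
    bg_mean <- mean(ai$pixels[!shaft_any])
    for (b in seq_len(nrow(ai$boxes))) {
      bx <- ai$boxes[b, ]
      expect_gte(bx$x, 0); expect_gte(bx$y, 0)
      expect_lte(bx$x + bx$w, W); expect_lte(bx$y + bx$h, H)
      inbox <- ai$pixels[(bx$y + 1):(bx$y + bx$h), (bx$x + 1):(bx$x + bx$w)]
      expect_gt(mean(inbox), bg_mean)
    }
    # exactly two half labels per box
    expect_equal(as.vector(table(ai$half_labels$box_id)), rep(2L, nrow(ai$boxes)))
    expect_setequal(unique(ai$half_labels$box_id), ai$boxes$id)
  }
})

test_that("a half is damaged exactly when a wedge was rendered on that side", {
  ai <- generate_radiograph(small_spec(seed = 11, n_implants = 2,
                                       defect_present = TRUE,
                                       defect_sides = list("left", character(0))))
  for (r in seq_len(nrow(ai$half_labels))) {
    key <- paste0(ai$half_labels$box_id[r], "_", ai$half_labels$side[r])
    expect_identical(ai$half_labels$label[r] == "damaged",
                     key %in% names(ai$masks$wedge))
  }
})

test_that("the erosion wedge darkens by close to the configured amount", {
  # vertical shaft so the mirrored region is clean background; bright
  # background keeps the darkened pixels away from the 8-bit floor
  ai <- generate_radiograph(small_spec(seed = 3, defect_present = TRUE,
                                       defect_sides = list("right"),
                                       defect_depth_threads = 4,
                                       background_mean = 120,
                                       background_noise_sd = 5,
                                       rotation_max_deg = 0, n_teeth = 0))
  wmask <- ai$masks$wedge[["1_right"]]
  shaft_cols <- which(colSums(ai$masks$shaft[[1]]) > 0) - 1
  cx <- mean(range(shaft_cols))             # implant center column, 0-based
  idx <- which(wmask, arr.ind = TRUE)
  mirror_cols <- round(2 * cx - (idx[, 2] - 1)) + 1
  ok <- mirror_cols >= 1 & mirror_cols <= ncol(ai$pixels)
  mirrored <- ai$pixels[cbind(idx[ok, 1], mirror_cols[ok])]
  diff <- mean(mirrored) - mean(ai$pixels[wmask])
  expect_lt(abs(diff - 80), 5)
})

test_that("dataset generation hits the damaged fraction and is deterministic", {
  s <- small_spec()
  ds <- generate_dataset(s, 10, 0.5, seed = 3)
  labs <- unlist(lapply(ds, function(a) a$half_labels$label))
  expect_length(ds, 10)
  expect_equal(sum(labs == "damaged"), 10)   # half of 20 half-labels

  ds0 <- generate_dataset(s, 5, 0, seed = 3)
  expect_true(all(unlist(lapply(ds0, function(a) a$half_labels$label)) == "healthy"))

  l1 <- unlist(lapply(generate_dataset(s, 20, 0.4, seed = 1),
                      function(a) a$half_labels$label))
  l2 <- unlist(lapply(generate_dataset(s, 20, 0.4, seed = 1),
                      function(a) a$half_labels$label))
  expect_identical(l1, l2)

  expect_error(generate_dataset(s, 0, 0.5), "n_images")
})

test_that("annotations round-trip through PNG + JSON", {
  ai <- generate_radiograph(small_spec(seed = 9, defect_present = TRUE))
  dir <- withr::local_tempdir()
  write_annotated(ai, dir, "img001")
  back <- read_annotated(file.path(dir, "img001.json"))
  expect_equal(back$boxes$x, ai$boxes$x)
  expect_equal(back$boxes$w, ai$boxes$w)
  expect_equal(back$half_labels$label, ai$half_labels$label)
  expect_equal(back$pixels, ai$pixels, ignore_attr = TRUE)
})
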