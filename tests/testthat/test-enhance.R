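test_that("histogram equalization follows the cdf mapping exactly", {
  # constant image: the sole level has cumulative probability 1 -> 255
  expect_true(all(equalize_histogram(matrix(42, 5, 7)) == 255))
  # two levels at 50%: floor(255 * 0.5) = 127 and floor(255 * 1) = 255
  out <- equalize_histogram(matrix(c(10, 10, 200, 200), 2, 2))
  expect_equal(sort(unique(as.vector(out))), c(127, 255))
  # uniform ramp holding each level once: out = floor(255 (i + 1) / 256)
  ramp <- matrix(0:255, 16, 16)
  expect_equal(equalize_histogram(ramp), floor(255 * (ramp + 1) / 256))
})

test_that("equalization is monotone and near-uniform for rich images", {
  set.seed(5)
  img <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  out <- equalize_histogram(img)
  ord <- order(as.vector(img))
  expect_true(all(diff(out[ord]) >= 0))
  # cdf of the output within 1/L of uniform at every level
  cdf_out <- cumsum(tabulate(out + 1, 256)) / length(out)
  expect_lt(max(abs(cdf_out - (0:255 + 1) / 256)), 1 / 256 + 0.01)
})

test_that("adaptive equalization degenerates to global and keeps local contrast", {
  expect_true(all(adaptive_equalize(matrix(99, 20, 20), c(2, 2), 1) ==
                  adaptive_equalize(matrix(99, 20, 20), c(2, 2), 1)[1, 1]))
  set.seed(11)
  for (i in 1:5) {
    img <- matrix(sample(0:255, 30 * 40, TRUE), 30, 40)
    expect_lte(max(abs(adaptive_equalize(img, c(1, 1), 1) -
                       equalize_histogram(img))), 1)
  }
  # checkerboard of 8 px squares, 16 px tiles: every tile spans both levels
  # and keeps its full local contrast
  checker <- 255 * outer(0:63, 0:63, function(r, c) (r %/% 8 + c %/% 8) %% 2)
  out <- adaptive_equalize(checker, c(4, 4), 0.01)
  for (i in 0:3) for (j in 0:3) {
    tile <- out[i * 16 + 1:16, j * 16 + 1:16]
    expect_lt(min(tile), 64)
    expect_gt(max(tile), 192)
  }
  expect_error(adaptive_equalize(matrix(0, 8, 8), c(8, 8), 0.5), "tiles")
  expect_error(adaptive_equalize(matrix(0, 8, 8), c(2, 2), 0), "clip_limit")
})

test_that("the enhancement difference is an element-wise absolute difference", {
  a <- matrix(200, 10, 10)
  expect_true(all(enhancement_difference(a, a) == 0))
  expect_true(all(enhancement_difference(a, matrix(50, 10, 10)) == 150))
  set.seed(3)
  x <- matrix(sample(0:255, 100, TRUE), 10, 10)
  y <- matrix(sample(0:255, 100, TRUE), 10, 10)
  oracle <- matrix(0L, 10, 10)
  for (i in 1:10) for (j in 1:10) oracle[i, j] <- abs(x[i, j] - y[i, j])
  expect_equal(enhancement_difference(x, y), oracle, ignore_attr = TRUE)
  expect_error(enhancement_difference(x, matrix(0, 5, 5)), "mismatch")
})

test_that("gradient magnitude matches analytic fields", {
  expect_true(all(gradient_magnitude(matrix(7, 5, 5)) == 0))
  # vertical step: response confined to the two columns at the step
  step <- cbind(matrix(0, 6, 3), matrix(255, 6, 3))
  g <- gradient_magnitude(step)
  expect_true(all(g[, c(1, 2, 5, 6)] == 0))
  expect_true(all(g[, 3:4] > 0))
  # unit ramp: interior magnitude exactly 1
  ramp <- matrix(rep(0:9, each = 8), 8, 10)
  g2 <- gradient_magnitude(ramp)
  expect_true(all(g2[2:7, 2:9] == 1))
  expect_error(gradient_magnitude(matrix(0, 2, 5)), "3 x 3")
})

test_that("surface classification follows gate, range, and height rules", {
  p <- surface_params(range_window = 3, range_threshold = 40,
                      z_threshold = 128, gate_value = 30)
  const <- matrix(200, 10, 10)
  lab <- classify_surface(const, gradient_magnitude(const), p)
  expect_true(all(lab == "implant"))

  # gate precedence: darker than the gate is background even on a hard edge
  img <- matrix(200, 10, 10); img[, 6:10] <- 5
  lab2 <- classify_surface(img, gradient_magnitude(img), p)
  expect_true(all(lab2[, 7:10] == "background"))
  expect_true(any(lab2 == "edge"))

  # two flat regions split by the height threshold
  img3 <- matrix(90, 20, 20); img3[, 11:20] <- 220
  lab3 <- classify_surface(img3, gradient_magnitude(img3), p)
  expect_true(all(lab3[, 1:8] == "gum"))
  expect_true(all(lab3[, 13:20] == "implant"))

  expect_error(surface_params(range_window = 4), "odd")
  expect_error(surface_params(gate_value = 200, z_threshold = 100), "gate_value")
})

test_that("surface labels recover the generator's implant region", {
  ch <- damaged_chain()
  gray <- ch$crop$pixels
  sb <- ch$crop$source_box
  truth_shaft <- ch$ai$masks$shaft[[1]][(sb$y + 1):(sb$y + sb$h),
                                        (sb$x + 1):(sb$x + sb$w)]
  lab <- classify_surface(gray, gradient_magnitude(gray), auto_surface_params(gray))
  flat <- lab != "edge"
  # on flat pixels, 'implant' labels and the true shaft agree almost everywhere
  expect_gt(mean((lab == "implant")[flat] == truth_shaft[flat]), 0.95)
})

test_that("colorization uses the fixed palette plus gray edges and a red line", {
  gray <- matrix(100, 12, 10)
  lab <- matrix("implant", 12, 10)
  eh <- colorize(gray, lab, 3)
  expect_s3_class(eh, "enhanced_half")
  for (r in c(1, 6, 12)) for (c in c(1, 5, 10)) {
    expect_equal(rgb_at(eh$pixels, r, c),
                 if (r == 4) "255,0,0" else "0,255,0")
  }
  # mixed map: palette colors only, edges keep their gray
  lab2 <- matrix("background", 12, 10)
  lab2[2, ] <- "gum"; lab2[5, 3] <- "edge"; lab2[7, ] <- "implant"
  eh2 <- colorize(gray, lab2, 0)
  expect_equal(rgb_at(eh2$pixels, 1, 1), "255,0,0")       # row 0 red
  expect_equal(rgb_at(eh2$pixels, 2, 4), "255,165,0")
  expect_equal(rgb_at(eh2$pixels, 5, 3), "100,100,100")
  expect_equal(rgb_at(eh2$pixels, 7, 2), "0,255,0")
  expect_equal(rgb_at(eh2$pixels, 12, 9), "0,0,0")
  expect_error(colorize(gray, lab, 12), "reference_row")
  expect_error(colorize(gray, lab, -1), "reference_row")
})

test_that("the preprocessing chain is deterministic and separates the classes", {
  ch <- damaged_chain()
  a <- preprocess_half(ch$halves$right, platform_row = 0)
  b <- preprocess_half(ch$halves$right, platform_row = 0)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$label_map, b$label_map)

  healthy <- preprocess_half(ch$halves$left, platform_row = 0)
  damaged <- preprocess_half(ch$halves$right, platform_row = 0)
  gum_frac <- function(eh) mean(eh$label_map == "gum")
  expect_gt(abs(gum_frac(damaged) - gum_frac(healthy)), 0.10)

  expect_error(preprocess_half(matrix(5, 1, 1)), ".")
})
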