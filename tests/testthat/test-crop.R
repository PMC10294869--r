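test_that("expand_box widens horizontally and clips at the borders", {
  b <- list(x = 100, y = 50, w = 80, h = 200)
  expect_equal(expand_box(b, 20, c(500, 400)), list(x = 80, y = 50, w = 120, h = 200))
  expect_equal(expand_box(b, 0, c(500, 400)), list(x = 100, y = 50, w = 80, h = 200))
  expect_equal(expand_box(list(x = 5, y = 0, w = 40, h = 100), 20, c(300, 300)),
               list(x = 0, y = 0, w = 65, h = 100))
  expect_error(expand_box(b, -1, c(500, 400)), "margin")
})

test_that("binarization recovers the generator's shaft mask", {
  ch <- damaged_chain()
  sb <- ch$crop$source_box
  truth <- ch$ai$masks$shaft[[1]][(sb$y + 1):(sb$y + sb$h),
                                  (sb$x + 1):(sb$x + sb$w)]
  expect_lt(mean(ch$mask != truth), 0.02)
  expect_error(binarize_implant(matrix(128, 20, 20)), "degenerate|uniform")
})

test_that("binarization keeps a single bright component", {
  img <- matrix(20, 50, 50)
  img[10:40, 20:30] <- 220          # main shaft
  img[2:4, 2:4] <- 220              # small distractor
  mask <- binarize_implant(img)
  expect_true(all(mask[10:40, 20:30]))
  expect_false(any(mask[2:4, 2:4]))   # largest component only
})

test_that("midline fit matches symmetric and analytic cases", {
  mask <- matrix(FALSE, 210, 120)
  mask[11:201, 41:61] <- TRUE        # columns 40-60, rows 10-200 (0-based)
  line <- fit_midline(mask)
  expect_equal(line$beta1, 0, tolerance = 1e-12)
  expect_equal(line$beta0, 50, tolerance = 1e-12)

  # pixels at column 10 + 0.5 r: fit equals the closed-form least squares
  r <- 0:99
  cols <- round(10 + 0.5 * r)
  mask2 <- matrix(FALSE, 100, 80)
  mask2[cbind(r + 1, cols + 1)] <- TRUE
  line2 <- fit_midline(mask2)
  X <- cbind(1, r)
  beta <- solve(t(X) %*% X, t(X) %*% cols)
  expect_equal(line2$beta0, beta[1], tolerance = 1e-9)
  expect_equal(line2$beta1, beta[2], tolerance = 1e-9)
  expect_equal(line2$beta0, 10, tolerance = 0.3)
  expect_equal(line2$beta1, 0.5, tolerance = 0.01)

  expect_error(fit_midline(matrix(FALSE, 5, 5)), "2 distinct rows")
  m1 <- matrix(FALSE, 5, 5); m1[3, ] <- TRUE
  expect_error(fit_midline(m1), "2 distinct rows")
})

test_that("midline of a rotated bar stays within 0.5 px RMS of the analytic centerline", {
  theta <- 5 * pi / 180
  H <- 200; W <- 120
  cx <- 60; cy <- 100; halfw <- 10; halfl <- 90
  mask <- matrix(FALSE, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      # rotate into the bar frame
      u <- (c - 1 - cx) * cos(theta) + (r - 1 - cy) * sin(theta)
      v <- -(c - 1 - cx) * sin(theta) + (r - 1 - cy) * cos(theta)
      if (abs(u) <= halfw && abs(v) <= halfl) mask[r, c] <- TRUE
    }
  }
  line <- fit_midline(mask)
  rows <- which(apply(mask, 1, any)) - 1
  rows <- rows[rows > min(rows) + 5 & rows < max(rows) - 5]  # full-width rows
  analytic <- cx - tan(theta) * (rows - cy)
  fitted <- line$beta0 + line$beta1 * rows
  expect_lt(sqrt(mean((fitted - analytic)^2)), 0.5)
})

test_that("least-squares fit equals the normal-equations oracle on random masks", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(30:200, 1)
    rows <- sample(0:99, n, replace = TRUE)
    if (length(unique(rows)) < 2) next
    cols <- pmin(pmax(round(20 + 0.3 * rows + rnorm(n, 0, 4)), 0), 79)
    mask <- matrix(FALSE, 100, 80)
    mask[unique(cbind(rows + 1, cols + 1))] <- TRUE
    idx <- which(mask, arr.ind = TRUE)
    X <- cbind(1, idx[, 1] - 1)
    beta <- solve(t(X) %*% X, t(X) %*% (idx[, 2] - 1))
    line <- fit_midline(mask)
    expect_equal(line$beta0, beta[1], tolerance = 1e-9)
    expect_equal(line$beta1, beta[2], tolerance = 1e-9)
  }
})

test_that("splitting pads to equal widths and reconstructs exactly", {
  crop <- matrix(seq_len(100 * 100), 100, 100)
  hs <- split_halves(crop, structure(list(beta0 = 50, beta1 = 0),
                                     class = "regression_line"))
  expect_equal(dim(hs$left$pixels), c(100, 50))
  expect_equal(dim(hs$right$pixels), c(100, 50))
  expect_equal(hs$left$pad_columns, 0)
  expect_identical(unsplit_halves(hs$left, hs$right), crop * 1)

  hs40 <- split_halves(crop, structure(list(beta0 = 40, beta1 = 0),
                                       class = "regression_line"))
  expect_equal(ncol(hs40$left$pixels), 60)
  expect_equal(ncol(hs40$right$pixels), 60)
  expect_equal(hs40$left$pad_columns, 20)
  expect_equal(hs40$right$pad_columns, 0)
  expect_identical(unsplit_halves(hs40$left, hs40$right), crop * 1)

  tilted <- split_halves(crop, structure(list(beta0 = 30, beta1 = 0.3),
                                         class = "regression_line"))
  expect_gt(length(unique(attr(tilted$left, "cuts"))), 1)
  expect_identical(unsplit_halves(tilted$left, tilted$right), crop * 1)

  expect_error(split_halves(crop, structure(list(beta0 = -500, beta1 = 0),
                                            class = "regression_line")),
               "outside")
})

test_that("split conservation and mirror equivariance hold for random midlines", {
  set.seed(7)
  for (i in 1:10) {
    H <- sample(40:120, 1); W <- sample(40:120, 1)
    crop <- matrix(sample(0:255, H * W, TRUE), H, W)
    line <- structure(list(beta0 = runif(1, 0.3 * W, 0.7 * W) + 0.1,
                           beta1 = runif(1, -0.3, 0.3)),
                      class = "regression_line")
    hs <- split_halves(crop, line)
    expect_identical(unsplit_halves(hs$left, hs$right), crop * 1)

    # mirrored crop + mirrored midline swap the halves up to the boundary
    # column: the pixel straddling the cut must pick a side, so per row the
    # swapped widths may differ by at most one
    mcrop <- crop[, rev(seq_len(W))]
    mline <- structure(list(beta0 = (W - 1) - line$beta0, beta1 = -line$beta1),
                       class = "regression_line")
    mhs <- split_halves(mcrop, mline)
    expect_identical(unsplit_halves(mhs$left, mhs$right), mcrop * 1)
    expect_lte(max(abs(attr(mhs$left, "cuts") - (W - attr(hs$left, "cuts")))), 1)
  }
})

test_that("mirroring swaps the halves exactly when the cut is between columns", {
  crop <- matrix(sample(0:255, 80 * 70, TRUE), 80, 70)
  W <- ncol(crop)
  line <- structure(list(beta0 = 30.5, beta1 = 0), class = "regression_line")
  hs <- split_halves(crop, line)
  mline <- structure(list(beta0 = (W - 1) - 30.5, beta1 = 0),
                     class = "regression_line")
  mhs <- split_halves(crop[, rev(seq_len(W))], mline)
  expect_identical(attr(mhs$left, "cuts"), W - attr(hs$left, "cuts"))
  # mirrored left content = right content mirrored
  k <- attr(hs$left, "cuts")[1]
  expect_identical(mhs$left$pixels[, seq_len(W - k)],
                   crop[, rev((k + 1):W)] * 1)
})

test_that("the full crop chain of a generated implant is self-consistent", {
  ch <- damaged_chain()
  hs <- ch$halves
  expect_equal(dim(hs$left$pixels), dim(hs$right$pixels))
  expect_identical(unsplit_halves(hs$left, hs$right), ch$crop$pixels * 1)
  # midline is near-vertical for a mildly rotated shaft
  expect_lt(abs(hs$left$pad_columns - hs$right$pad_columns), ncol(ch$crop$pixels))
  expect_lt(abs(ch$line$beta1), 0.3)
})
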