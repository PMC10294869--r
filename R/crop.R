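#' Expand a detection box horizontally, clipped to the image
#'
#' The thread-only ROI deliberately excludes the gingiva flanking the
#' threads, but the damage assessment needs those flanking features, so the
#' box is widened by `margin` pixels on each side before cropping. Vertical
#' extent is unchanged. Clipping at the image border is silent.
#'
#' @param box List or one-row data frame with `x, y, w, h` (0-based pixels).
#' @param margin Pixels added on each horizontal side (>= 0).
#' @param image_extent `c(width, height)` of the source image.
#' @return The expanded box (same shape as the input fields).
#' @export
expand_box <- function(box, margin, image_extent) {
  if (margin < 0) stop("expand_box: margin must be >= 0")
  x0 <- max(0, box$x - margin)
  x1 <- min(image_extent[1], box$x + box$w + margin)
  list(x = x0, y = box$y, w = x1 - x0, h = box$h)
}

#' Crop an implant region from a radiograph
#'
#' @param image Grayscale matrix (rows = y).
#' @param box Thread box (`x, y, w, h`, 0-based).
#' @param margin Horizontal expansion passed to [expand_box()] (default 20).
#' @return Object of class `implant_crop`: `pixels`, `source_box`, `margin`.
#' @export
crop_implant <- function(image, box, margin = 20) {
  eb <- expand_box(box, margin, c(ncol(image), nrow(image)))
  rows <- (eb$y + 1):(eb$y + eb$h)
  cols <- (eb$x + 1):(eb$x + eb$w)
  structure(list(pixels = image[rows, cols, drop = FALSE],
                 source_box = eb, margin = margin),
            class = "implant_crop")
}

#' Binarize a crop to extract the implant
#'
#' Global Otsu threshold (the implant is brighter than everything around
#' it), keeping only the largest connected foreground component so flanking
#' bright structures do not perturb the midline fit.
#'
#' @param crop An `implant_crop` or grayscale matrix.
#' @return Logical matrix: `TRUE` on the implant.
#' @export
binarize_implant <- function(crop) {
  px <- if (is.list(crop)) crop$pixels else crop
  if (length(px) == 0) stop("binarize_implant: empty crop")
  if (diff(range(px)) == 0)
    stop("binarize_implant: uniform crop, threshold is degenerate")
  th <- otsu_threshold(px)
  mask <- as_gray8(px) >= th
  lab <- EBImage::bwlabel(mask * 1)
  if (max(lab) > 1) {
    sizes <- tabulate(lab[lab > 0])
    mask <- lab == which.max(sizes)
  }
  mask
}

#' Fit the implant midline by least squares
#'
#' Ordinary least squares of column index on row index over all foreground
#' pixels (0-based coordinates). The implant's long axis is near-vertical in
#' a periapical film, so regressing the column on the row yields the
#' centerline directly; this is the same fit one gets by laying the implant
#' along the abscissa and fitting `y = beta0 + beta1 * x`, without the
#' rotation step.
#'
#' @param mask Logical matrix with foreground in at least 2 distinct rows.
#' @return Object of class `regression_line` with `beta0` (intercept,
#'   pixels) and `beta1` (slope, columns per row).
#' @export
fit_midline <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0 || length(unique(idx[, 1])) < 2)
    stop("fit_midline: foreground must span at least 2 distinct rows")
  rows <- idx[, 1] - 1
  cols <- idx[, 2] - 1
  fit <- lm.fit(cbind(1, rows), cols)
  structure(list(beta0 = unname(fit$coefficients[1]),
                 beta1 = unname(fit$coefficients[2])),
            class = "regression_line")
}

#' @export
print.regression_line <- function(x, ...) {
  cat(sprintf("<regression_line col = %.3f + %.4f * row>\n", x$beta0, x$beta1))
  invisible(x)
}

midline_cuts <- function(line, n_rows, width) {
  cut <- line$beta0 + line$beta1 * (seq_len(n_rows) - 1)
  if (all(cut < -0.5) || all(cut > width - 0.5))
    stop("split_halves: midline lies entirely outside the crop")
  ## pixel j (0-based) goes left when its center is at or left of the cut
  pmin(pmax(floor(cut + 0.5), 0L), width)
}

#' Split a crop into left and right halves along the midline
#'
#' Each pixel is assigned to the side of the midline evaluated at its row
#' (pixels exactly on the midline go left). Both halves are padded with
#' zeros on their cut edge to the width of the wider half, so the pair has
#' identical dimensions; the union of the two halves minus padding
#' reconstructs the crop exactly.
#'
#' @param crop An `implant_crop` or grayscale matrix.
#' @param line A [fit_midline()] result.
#' @return List of two objects of class `half_crop` (`left`, `right`), each
#'   with `pixels`, `side`, `pad_columns`, and the per-row cut positions in
#'   `attr(, "cuts")`.
#' @export
split_halves <- function(crop, line) {
  px <- if (is.list(crop)) crop$pixels else crop
  H <- nrow(px); W <- ncol(px)
  k <- midline_cuts(line, H, W)
  common <- max(max(k), W - min(k))
  left <- matrix(0, H, common)
  right <- matrix(0, H, common)
  for (r in seq_len(H)) {
    if (k[r] > 0) left[r, seq_len(k[r])] <- px[r, seq_len(k[r])]
    nr <- W - k[r]
    if (nr > 0) right[r, (common - nr + 1):common] <- px[r, (k[r] + 1):W]
  }
  mk <- function(pixels, side, pad) {
    structure(list(pixels = pixels, side = side, pad_columns = as.integer(pad)),
              class = "half_crop", cuts = k, crop_width = W)
  }
  list(left = mk(left, "left", common - max(k)),
       right = mk(right, "right", common - (W - min(k))))
}

#' Reassemble a crop from its two halves
#'
#' Inverse of [split_halves()]; used to verify that the split is lossless.
#'
#' @param left,right The two `half_crop` objects from one split.
#' @return The reconstructed crop matrix.
#' @export
unsplit_halves <- function(left, right) {
  k <- attr(left, "cuts")
  W <- attr(left, "crop_width")
  common <- ncol(left$pixels)
  H <- nrow(left$pixels)
  out <- matrix(0, H, W)
  for (r in seq_len(H)) {
    if (k[r] > 0) out[r, seq_len(k[r])] <- left$pixels[r, seq_len(k[r])]
    nr <- W - k[r]
    if (nr > 0) out[r, (k[r] + 1):W] <- right$pixels[r, (common - nr + 1):common]
  }
  out
}
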