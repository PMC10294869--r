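as_gray8 <- function(gray) {
  if (length(dim(gray)) == 3) gray <- apply(gray, c(1, 2), mean)
  if (!is.matrix(gray) || length(gray) == 0) stop("expected a non-empty grayscale matrix")
  matrix(as.integer(clamp8(round(gray))), nrow(gray), ncol(gray))
}

#' Global histogram equalization
#'
#' Remaps gray levels through the image's cumulative distribution:
#' `p(i) = n_i / n` over `L = 256` levels, `cdf(i) = sum_{j<=i} p(j)`, and
#' `out = floor(255 * cdf(in))`. The plain `cdf x 255` scaling is used with
#' no cdf-minimum renormalization, so a constant image maps to 255 (the sole
#' occupied level has cumulative probability 1). The mapping is monotone in
#' the input gray level.
#'
#' @param gray Matrix with values 0-255 (rounded to integers on entry).
#' @return Matrix of integers 0-255, same dimensions.
#' @export
equalize_histogram <- function(gray) {
  v <- as_gray8(gray)
  counts <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(v)
  map <- as.integer(floor(255 * cdf))
  matrix(map[v + 1L], nrow(v), ncol(v))
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise equalization with histogram clipping and bilinear interpolation
#' between neighbouring tile mappings. Each tile's histogram is clipped at
#' `clip_limit` times the tile pixel count (excess mass redistributed
#' uniformly) and converted to a `floor(255 * cdf)` mapping -- the same
#' scaling convention as [equalize_histogram()], so with a single tile and
#' `clip_limit = 1` the operator degenerates to global equalization.
#'
#' @param gray Matrix with values 0-255.
#' @param tiles Integer vector `c(rows, cols)` of the tile grid.
#' @param clip_limit Fraction in (0, 1]: per-bin histogram cap as a fraction
#'   of the tile's pixel count.
#' @return Matrix of integers 0-255.
#' @export
adaptive_equalize <- function(gray, tiles = c(8, 8), clip_limit = 0.01) {
  v <- as_gray8(gray)
  H <- nrow(v); W <- ncol(v)
  tr <- as.integer(tiles[1]); tc <- as.integer(tiles[2])
  if (clip_limit <= 0 || clip_limit > 1) stop("clip_limit must be in (0, 1]")
  rb <- round(seq(0, H, length.out = tr + 1))
  cb <- round(seq(0, W, length.out = tc + 1))
  if (any(diff(rb) < 2) || any(diff(cb) < 2))
    stop("adaptive_equalize: tiles smaller than 2 x 2; reduce the tile grid")

  maps <- array(0L, dim = c(256, tr, tc))
  rcent <- ccent <- numeric(0)
  rcent <- (rb[-1] + rb[-(tr + 1)]) / 2 - 0.5   # tile centers, 0-based rows
  ccent <- (cb[-1] + cb[-(tc + 1)]) / 2 - 0.5
  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      tv <- v[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1]]
      counts <- tabulate(tv + 1L, nbins = 256L)
      cap <- clip_limit * length(tv)
      excess <- sum(pmax(counts - cap, 0))
      counts <- pmin(counts, cap) + excess / 256
      maps[, i, j] <- as.integer(floor(255 * cumsum(counts) / sum(counts)))
    }
  }

  ## bilinear interpolation between the four surrounding tile mappings
  interp_idx <- function(pos, centers) {
    k <- findInterval(pos, centers)
    i0 <- pmax(k, 1L); i1 <- pmin(k + 1L, length(centers))
    i0 <- pmin(i0, length(centers))
    denom <- centers[i1] - centers[i0]
    wt <- ifelse(denom > 0, (pos - centers[i0]) / pmax(denom, 1e-12), 0)
    wt[k < 1] <- 0
    list(i0 = i0, i1 = i1, w = pmin(pmax(wt, 0), 1))
  }
  ri <- interp_idx(seq_len(H) - 1, rcent)
  ci <- interp_idx(seq_len(W) - 1, ccent)

  vi <- v + 1L
  R0 <- matrix(ri$i0, H, W); R1 <- matrix(ri$i1, H, W)
  C0 <- matrix(ci$i0, H, W, byrow = TRUE); C1 <- matrix(ci$i1, H, W, byrow = TRUE)
  WR <- matrix(ri$w, H, W); WC <- matrix(ci$w, H, W, byrow = TRUE)
  out <- (1 - WR) * (1 - WC) * maps[cbind(c(vi), c(R0), c(C0))] +
         (1 - WR) * WC       * maps[cbind(c(vi), c(R0), c(C1))] +
         WR       * (1 - WC) * maps[cbind(c(vi), c(R1), c(C0))] +
         WR       * WC       * maps[cbind(c(vi), c(R1), c(C1))]
  matrix(as.integer(round(out)), H, W)
}

#' Absolute difference of two enhanced images
#'
#' The global and adaptive equalization results are subtracted to isolate the
#' structure that only local equalization brings out; the absolute value is
#' taken so the result stays in the 8-bit range.
#'
#' @param he,ahe Matrices of identical dimensions, values 0-255.
#' @return Matrix of integers 0-255.
#' @export
enhancement_difference <- function(he, ahe) {
  if (!all(dim(he) == dim(ahe))) stop("enhancement_difference: shape mismatch")
  matrix(as.integer(abs(as_gray8(he) - as_gray8(ahe))), nrow(he), ncol(he))
}

#' Gradient magnitude field
#'
#' `sqrt(gx^2 + gy^2)` with central differences in the interior and one-sided
#' differences at the borders. This is the height field of the 3-D edge map
#' used to separate edge from flat pixels.
#'
#' @param gray Matrix, at least 3 x 3.
#' @return Numeric matrix of the same dimensions.
#' @export
gradient_magnitude <- function(gray) {
  if (!is.matrix(gray) || nrow(gray) < 3 || ncol(gray) < 3)
    stop("gradient_magnitude: image must be at least 3 x 3")
  H <- nrow(gray); W <- ncol(gray)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gx[, 2:(W - 1)] <- (gray[, 3:W] - gray[, 1:(W - 2)]) / 2
  gx[, 1] <- gray[, 2] - gray[, 1]
  gx[, W] <- gray[, W] - gray[, W - 1]
  gy[2:(H - 1), ] <- (gray[3:H, ] - gray[1:(H - 2), ]) / 2
  gy[1, ] <- gray[2, ] - gray[1, ]
  gy[H, ] <- gray[H, ] - gray[H - 1, ]
  sqrt(gx^2 + gy^2)
}

local_range <- function(gray, window = 3) {
  h <- (window - 1) %/% 2
  H <- nrow(gray); W <- ncol(gray)
  mx <- matrix(-Inf, H, W); mn <- matrix(Inf, H, W)
  for (dy in -h:h) {
    rs <- pmin(pmax(seq_len(H) + dy, 1L), H)
    valid_r <- seq_len(H) + dy >= 1 & seq_len(H) + dy <= H
    for (dx in -h:h) {
      cs <- pmin(pmax(seq_len(W) + dx, 1L), W)
      valid_c <- seq_len(W) + dx >= 1 & seq_len(W) + dx <= W
      sh <- gray[rs, cs, drop = FALSE]
      sh[!valid_r, ] <- NA; sh[, !valid_c] <- NA
      mx <- pmax(mx, sh, na.rm = TRUE); mn <- pmin(mn, sh, na.rm = TRUE)
    }
  }
  mx - mn
}

#' Surface-classification parameters
#'
#' Thresholds for [classify_surface()]: a pixel whose local min-max range
#' (window `range_window`) exceeds `range_threshold` lies on an edge;
#' otherwise its height separates implant (above `z_threshold`) from gum, and
#' anything below `gate_value` is gated to black as background. Invariant:
#' `0 <= gate_value <= z_threshold <= 255`.
#'
#' @param range_window Odd window size in pixels (>= 3).
#' @param range_threshold Gray-level range above which a pixel is an edge.
#' @param z_threshold Gray level separating implant from gum.
#' @param gate_value Gray level below which pixels are blacked out.
#' @return Object of class `surface_params`.
#' @seealso [auto_surface_params()] for data-driven defaults.
#' @export
surface_params <- function(range_window = 3, range_threshold = 40,
                           z_threshold = 128, gate_value = 30) {
  if (range_window < 3 || range_window %% 2 == 0)
    stop("surface_params: range_window must be odd and >= 3")
  if (!(gate_value >= 0 && gate_value <= z_threshold && z_threshold <= 255))
    stop("surface_params: need 0 <= gate_value <= z_threshold <= 255")
  structure(list(range_window = as.integer(range_window),
                 range_threshold = range_threshold,
                 z_threshold = z_threshold, gate_value = gate_value),
            class = "surface_params")
}

#' Derive surface-classification thresholds from an image
#'
#' Otsu splits computed from the image itself: the range threshold from the
#' local-range field, the implant/gum threshold from the intensities of flat
#' (non-edge) pixels, and the background gate from the flat pixels below the
#' implant/gum threshold. All three can be overridden via [surface_params()].
#'
#' @param gray Working grayscale image, values 0-255.
#' @param range_window Odd window size for the range filter.
#' @return A [surface_params()] object.
#' @export
auto_surface_params <- function(gray, range_window = 3) {
  v <- as_gray8(gray)
  rng <- local_range(v, range_window)
  range_threshold <- otsu_threshold(rng)
  flat <- v[rng <= range_threshold]
  if (length(unique(flat)) < 2) flat <- as.vector(v)
  z <- otsu_threshold(flat)
  low <- flat[flat <= z]
  gate <- if (length(unique(low)) >= 2) otsu_threshold(low) else max(0, z - 1)
  gate <- min(gate, z)
  surface_params(range_window, range_threshold, z, gate)
}

otsu_threshold <- function(x) {
  x <- as.integer(clamp8(round(as.numeric(x))))
  if (length(unique(x)) < 2) stop("otsu_threshold: degenerate (uniform) input")
  EBImage::otsu(matrix(x / 255, nrow = 1), range = c(0, 1), levels = 256) * 255
}

#' Label pixels as edge / implant / gum / background
#'
#' Gate precedence first: a pixel darker than `gate_value` is background
#' regardless of its neighbourhood. Otherwise a pixel is an edge when its
#' local min-max range (or the supplied gradient magnitude) exceeds
#' `range_threshold`; remaining flat pixels are implant when brighter than
#' `z_threshold`, else gum.
#'
#' @param original Working grayscale image, values 0-255.
#' @param grad Gradient-magnitude field from [gradient_magnitude()] (same
#'   dimensions), the 3-D edge map consulted alongside the range filter.
#' @param params A [surface_params()].
#' @return Character matrix with values `"edge"`, `"implant"`, `"gum"`,
#'   `"background"`.
#' @export
classify_surface <- function(original, grad, params) {
  stopifnot(inherits(params, "surface_params"))
  v <- as_gray8(original)
  if (!all(dim(grad) == dim(v))) stop("classify_surface: grad shape mismatch")
  rng <- local_range(v, params$range_window)
  labels <- matrix("background", nrow(v), ncol(v))
  notbg <- v >= params$gate_value
  edge <- notbg & (rng > params$range_threshold | grad > params$range_threshold)
  labels[notbg & !edge & v > params$z_threshold] <- "implant"
  labels[notbg & !edge & v <= params$z_threshold] <- "gum"
  labels[edge] <- "edge"
  labels
}

PALETTE <- list(implant = c(0, 255, 0), gum = c(255, 165, 0),
                background = c(0, 0, 0), reference = c(255, 0, 0))

#' Color-code a labeled half-image and draw the damage reference line
#'
#' Implant pixels become green, gum orange, background black; edge pixels
#' keep their working-image gray value so boundary structure survives the
#' recoloring. Row `reference_row` (0-based) is overwritten with pure red:
#' it marks the implant platform, the clinical reference against which
#' erosion to the first thread is judged.
#'
#' @param half A `half_crop`, `implant_crop`, or grayscale matrix (the
#'   enhanced working image).
#' @param labels Label map from [classify_surface()].
#' @param reference_row 0-based row index of the red reference line.
#' @return Object of class `enhanced_half`: list with `pixels`
#'   (h x w x 3 array, 0-255), `label_map`, `reference_row`.
#' @export
colorize <- function(half, labels, reference_row) {
  gray <- if (is.list(half)) half$pixels else half
  gray <- as_gray8(gray)
  if (!all(dim(labels) == dim(gray))) stop("colorize: label map shape mismatch")
  if (reference_row < 0 || reference_row >= nrow(gray))
    stop("colorize: reference_row outside the image")
  px <- array(0, dim = c(dim(gray), 3))
  for (k in 1:3) {
    ch <- matrix(0, nrow(gray), ncol(gray))
    ch[labels == "implant"] <- PALETTE$implant[k]
    ch[labels == "gum"] <- PALETTE$gum[k]
    ch[labels == "edge"] <- gray[labels == "edge"]
    ch[reference_row + 1, ] <- PALETTE$reference[k]
    px[, , k] <- ch
  }
  structure(list(pixels = px, label_map = labels,
                 reference_row = as.integer(reference_row)),
            class = "enhanced_half")
}

#' Full enhancement chain for one half-implant image
#'
#' Composition of the preprocessing stages: global equalization, adaptive
#' equalization, their absolute difference, overlay of the difference onto
#' the original by pixel-wise maximum (boundary boost), gradient magnitude,
#' surface labeling, and color coding with the platform reference line. The
#' chain is deterministic.
#'
#' @param half A `half_crop` or grayscale matrix, values 0-255.
#' @param params Optional [surface_params()]; derived from the overlay image
#'   via [auto_surface_params()] when `NULL`.
#' @param platform_row 0-based row of the implant platform in half-crop
#'   coordinates (default 0: the top row of the detector's thread box, which
#'   is where the crop starts).
#' @param tiles,clip_limit Passed to [adaptive_equalize()]; the tile grid is
#'   shrunk automatically so tiles stay at least 4 pixels on a side.
#' @return An `enhanced_half` (see [colorize()]).
#' @export
preprocess_half <- function(half, params = NULL, platform_row = 0,
                            tiles = c(8, 8), clip_limit = 0.01) {
  gray <- if (is.list(half)) half$pixels else half
  gray <- as_gray8(gray)
  tiles <- pmax(1L, pmin(as.integer(tiles), dim(gray) %/% 4L))
  he <- equalize_histogram(gray)
  ahe <- adaptive_equalize(gray, tiles = tiles, clip_limit = clip_limit)
  dif <- enhancement_difference(he, ahe)
  overlay <- pmax(gray, dif)
  grad <- gradient_magnitude(overlay)
  if (is.null(params)) params <- auto_surface_params(overlay)
  labels <- classify_surface(overlay, grad, params)
  colorize(overlay, labels, platform_row)
}
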