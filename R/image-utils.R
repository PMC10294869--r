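#' Read a radiograph image as an 8-bit grayscale matrix
#'
#' PNG (or single-frame grayscale/RGB) input is collapsed to one channel by
#' averaging and scaled to the 0-255 range used throughout the package.
#' Matrices are oriented rows = y (top to bottom), columns = x.
#'
#' @param path Path to a PNG file.
#' @return Numeric matrix with integer values in 0-255.
#' @export
read_radiograph <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- apply(px[, , 1:min(3, dim(px)[3]), drop = FALSE], c(1, 2), mean)
  round(px * 255)
}

#' Write a grayscale matrix or color array as PNG
#'
#' @param pixels Matrix (gray) or h x w x 3 array, values 0-255.
#' @param path Output path.
#' @export
write_radiograph <- function(pixels, path) {
  png::writePNG(pmin(pmax(pixels / 255, 0), 1), path)
  invisible(path)
}

#' Replicate a grayscale image to three channels
#'
#' The classifier input is 3-channel; synthetic radiographs are stored as a
#' single channel and replicated on demand.
#'
#' @param gray Numeric matrix.
#' @return h x w x 3 array.
#' @export
to_rgb <- function(gray) {
  if (length(dim(gray)) == 3) return(gray)
  array(rep(gray, 3), dim = c(dim(gray), 3))
}

clamp8 <- function(x) pmin(pmax(x, 0), 255)

#' Bilinear image resize
#'
#' @param img Matrix or h x w x 3 array.
#' @param height,width Output dimensions in pixels.
#' @return Resized image of the same arity.
#' @export
resize_image <- function(img, height, width) {
  if (length(dim(img)) == 3) {
    out <- array(0, dim = c(height, width, dim(img)[3]))
    for (k in seq_len(dim(img)[3])) out[, , k] <- cpp_resize_bilinear(img[, , k], height, width)
    out
  } else {
    cpp_resize_bilinear(img, height, width)
  }
}

#' Aspect-preserving resize with symmetric zero padding
#'
#' Scales the image so it fits inside `height` x `width` without distortion,
#' then pads the short dimension symmetrically with black. Used to bring
#' half-implant crops to the fixed classifier input frame: both stretching and
#' over-padding degrade the damage features, so the scale is maximal subject
#' to preserving aspect ratio.
#'
#' @param img Matrix or h x w x 3 array, values 0-255.
#' @param height,width Target frame in pixels.
#' @return Image of dimension `height` x `width` (x 3 if input was color).
#' @export
resize_pad <- function(img, height, width) {
  d <- dim(img)
  s <- min(height / d[1], width / d[2])
  nh <- max(1L, round(d[1] * s))
  nw <- max(1L, round(d[2] * s))
  small <- resize_image(img, nh, nw)
  top <- (height - nh) %/% 2
  left <- (width - nw) %/% 2
  if (length(d) == 3) {
    out <- array(0, dim = c(height, width, d[3]))
    out[top + seq_len(nh), left + seq_len(nw), ] <- small
  } else {
    out <- matrix(0, height, width)
    out[top + seq_len(nh), left + seq_len(nw)] <- small
  }
  out
}
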