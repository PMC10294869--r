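# Shared fixtures, generated in code.

# small fast generator settings used across tests
small_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(image_width = 160, image_height = 160, n_implants = 1,
         thread_pitch = 9, shaft_width = 16, defect_darkening = 80,
         seed = seed),
    list(...))
  do.call(synth_spec, args)
}

# one damaged radiograph plus its crop/mask chain, cached per session
damaged_chain <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ai <- generate_radiograph(small_spec(seed = 7, defect_present = TRUE,
                                           defect_sides = list("right")))
      crop <- crop_implant(ai$pixels, ai$boxes[1, ], margin = 10)
      mask <- binarize_implant(crop)
      line <- fit_midline(mask)
      halves <- split_halves(crop, line)
      cache <<- list(ai = ai, crop = crop, mask = mask, line = line,
                     halves = halves)
    }
    cache
  }
})

# random box data frame in an img_w x img_h image
random_boxes <- function(n, img_w = 200, img_h = 200) {
  data.frame(x = runif(n, 0, img_w - 40), y = runif(n, 0, img_h - 40),
             w = runif(n, 10, 40), h = runif(n, 10, 40),
             confidence = runif(n))
}

rgb_at <- function(arr, r, c) paste(arr[r, c, ], collapse = ",")
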