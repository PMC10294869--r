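#' Specification for a synthetic periapical radiograph
#'
#' Describes one synthetic film: geometry and intensity of the implant
#' shaft(s), the textured gingiva/bone background, and the optional erosion
#' defect. Clinical periapical image sets are not publicly available, so this
#' generator emulates the structure the analysis pipeline relies on: implants
#' render brighter than the surrounding tissue, threads form a periodic
#' crest/trough pattern orthogonal to the shaft axis, and peri-implantitis
#' appears as a dark wedge of bone subsidence abutting the coronal threads.
#'
#' @param image_width,image_height Image dimensions in pixels (>= 128).
#' @param n_implants Number of implants to place (0 allowed).
#' @param thread_pitch Pixels between successive thread crests.
#' @param shaft_width Width of the implant shaft in pixels.
#' @param shaft_intensity Gray level of the shaft (0-255); must exceed
#'   `background_mean` so implants render brighter than gingiva.
#' @param background_mean,background_noise_sd Gray-level mean and noise sd of
#'   the background texture.
#' @param defect_present Logical; render an erosion wedge?
#' @param defect_depth_threads How many coronal threads the erosion reaches
#'   (>= 1 when a defect is present; erosion to the first thread is the
#'   clinical damage criterion).
#' @param defect_darkening Gray-level drop applied inside the erosion wedge.
#' @param seed Integer seed; identical spec + seed gives bit-identical output.
#' @param defect_sides Optional list (length `n_implants`) of character
#'   vectors drawn from `c("left", "right")` naming the damaged side(s) of
#'   each implant. When `NULL` and `defect_present` is `TRUE`, one side per
#'   implant is chosen at random.
#' @param rotation_max_deg Maximum magnitude of the random shaft tilt in
#'   degrees (the midline-regression stage exists because threads need not be
#'   parallel to the image y-axis). Set 0 for perfectly vertical shafts.
#' @param n_teeth Number of smooth bright tooth-like blobs added as detection
#'   negatives (their boxes are recorded separately from implant boxes).
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(image_width = 256, image_height = 256, n_implants = 1,
                       thread_pitch = 14, shaft_width = 26,
                       shaft_intensity = 205, background_mean = 90,
                       background_noise_sd = 10, defect_present = FALSE,
                       defect_depth_threads = 3, defect_darkening = 60,
                       seed = 1, defect_sides = NULL, rotation_max_deg = 8,
                       n_teeth = 1) {
  spec <- list(
    image_width = as.integer(image_width), image_height = as.integer(image_height),
    n_implants = as.integer(n_implants), thread_pitch = as.integer(thread_pitch),
    shaft_width = as.integer(shaft_width), shaft_intensity = shaft_intensity,
    background_mean = background_mean, background_noise_sd = background_noise_sd,
    defect_present = isTRUE(defect_present),
    defect_depth_threads = as.integer(defect_depth_threads),
    defect_darkening = defect_darkening, seed = as.integer(seed),
    defect_sides = defect_sides, rotation_max_deg = rotation_max_deg,
    n_teeth = as.integer(n_teeth)
  )
  if (spec$image_width < 128 || spec$image_height < 128)
    stop("synth_spec: image dimensions must be at least 128 x 128")
  if (spec$shaft_intensity <= spec$background_mean)
    stop("synth_spec: shaft_intensity must exceed background_mean")
  if (spec$defect_present && spec$defect_depth_threads < 1)
    stop("synth_spec: defect_depth_threads must be >= 1 when defect_present")
  if (spec$n_implants < 0 || spec$thread_pitch < 2 || spec$shaft_width < 4)
    stop("synth_spec: invalid implant geometry")
  if (!is.null(defect_sides)) {
    if (!is.list(defect_sides) || length(defect_sides) != spec$n_implants ||
        !all(unlist(defect_sides) %in% c("left", "right")))
      stop("synth_spec: defect_sides must be a list of 'left'/'right' vectors, one per implant")
  }
  structure(spec, class = "synth_spec")
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate one synthetic annotated radiograph
#'
#' Renders `n_implants` non-overlapping threaded shafts on a textured
#' background, plus optional tooth-like negatives and erosion wedges. Ground
#' truth comprises thread-region bounding boxes (the ROI convention: the box
#' encloses only the threaded portion of the shaft, not the implant body
#' above it), per-half damaged/healthy labels, and pixel masks for the shaft
#' and each rendered wedge.
#'
#' Boxes use 0-based pixel coordinates, x rightward, y downward, half-open
#' `[x, x + w) x [y, y + h)`.
#'
#' @param spec A [synth_spec()].
#' @return An object of class `annotated_image`: list with elements `pixels`
#'   (integer-valued matrix 0-255), `boxes` (data frame `id, x, y, w, h`),
#'   `half_labels` (data frame `box_id, side, label`), `tooth_boxes`, and
#'   `masks` (logical matrices: `shaft[[id]]`, `wedge[["id_side"]]`).
#' @export
generate_radiograph <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_local_seed(spec$seed, render_radiograph(spec))
}

render_radiograph <- function(spec) {
  H <- spec$image_height; W <- spec$image_width
  ## textured background: white noise plus a smooth low-frequency field
  img <- matrix(rnorm(H * W, spec$background_mean, spec$background_noise_sd), H, W)
  coarse <- matrix(rnorm(ceiling(H / 16) * ceiling(W / 16), 0, spec$background_noise_sd * 0.4),
                   ceiling(H / 16), ceiling(W / 16))
  img <- img + cpp_resize_bilinear(coarse, H, W)

  thread_extent <- max(2L, round(0.25 * spec$shaft_width))
  half_core <- spec$shaft_width / 2
  len <- round(0.72 * H)
  y_top <- round(0.14 * H)
  collar <- round(0.2 * len)
  wedge_w0 <- round(0.9 * spec$shaft_width)
  reach <- half_core + thread_extent

  ## non-overlapping implant center columns: one horizontal slot per implant,
  ## jittered within the slack the slot leaves beyond the minimum separation
  margin_x <- ceiling(reach + wedge_w0 + tan(spec$rotation_max_deg * pi / 180) * len / 2 + 4)
  min_sep <- 2 * reach + wedge_w0 + 8
  centers <- numeric(0)
  if (spec$n_implants > 0) {
    n <- spec$n_implants
    usable <- W - 2 * margin_x
    extra <- usable - (n - 1) * min_sep
    if (extra < 0)
      stop(sprintf("generate_radiograph: could not place %d implants without overlap for this synth_spec (image %dx%d)",
                   n, W, H))
    ## gap method: uniform over feasible min-separated configurations
    centers <- margin_x + (seq_len(n) - 1) * min_sep + sort(runif(n, 0, extra))
  }

  boxes <- data.frame(id = integer(0), x = integer(0), y = integer(0), w = integer(0), h = integer(0))
  half_labels <- data.frame(box_id = integer(0), side = character(0), label = character(0))
  tooth_boxes <- data.frame(id = integer(0), x = integer(0), y = integer(0), w = integer(0), h = integer(0))
  masks <- list(shaft = list(), wedge = list())

  thetas <- if (spec$rotation_max_deg > 0) runif(spec$n_implants, -spec$rotation_max_deg, spec$rotation_max_deg) else rep(0, spec$n_implants)
  sides_list <- spec$defect_sides
  if (is.null(sides_list)) {
    sides_list <- if (spec$defect_present)
      lapply(seq_len(spec$n_implants), function(i) sample(c("left", "right"), 1)) else
      rep(list(character(0)), spec$n_implants)
  } else if (!spec$defect_present) {
    sides_list <- rep(list(character(0)), spec$n_implants)
  }

  for (i in seq_len(spec$n_implants)) {
    cx <- centers[i]
    slope <- tan(thetas[i] * pi / 180)
    y_mid <- y_top + len / 2
    thread_top <- y_top + collar
    y_bot <- y_top + len - 1
    taper_rows <- round(1.2 * spec$thread_pitch)
    shaft <- matrix(FALSE, H, W)
    for (y in y_top:y_bot) {
      cxy <- cx + slope * (y - y_mid)
      crest <- y >= thread_top && ((y - thread_top) %% spec$thread_pitch) < spec$thread_pitch / 2
      hw <- half_core + if (crest) thread_extent else 0
      if (y > y_bot - taper_rows) hw <- hw * (0.3 + 0.7 * (y_bot - y) / taper_rows)
      c0 <- max(1L, floor(cxy - hw) + 1L); c1 <- min(W, ceiling(cxy + hw))
      if (c1 >= c0) {
        img[y, c0:c1] <- spec$shaft_intensity + rnorm(c1 - c0 + 1, 0, 3)
        shaft[y, c0:c1] <- TRUE
      }
    }
    ## thread-only ROI: the box excludes the collar above the first thread
    thr_rows <- thread_top:y_bot
    cols_any <- which(colSums(shaft[thr_rows, , drop = FALSE]) > 0)
    x0 <- max(0L, min(cols_any) - 1L - 2L)          # 0-based with 2 px pad
    x1 <- min(W, max(cols_any) + 2L)                # exclusive
    y0 <- max(0L, thread_top - 1L - 2L)
    y1 <- min(H, y_bot + 2L)
    boxes <- rbind(boxes, data.frame(id = i, x = x0, y = y0, w = x1 - x0, h = y1 - y0))

    masks$shaft[[as.character(i)]] <- shaft
    depth_px <- min(spec$defect_depth_threads * spec$thread_pitch, y_bot - thread_top)
    for (side in c("left", "right")) {
      damaged <- side %in% sides_list[[i]]
      if (damaged) {
        wmask <- matrix(FALSE, H, W)
        for (k in 0:(depth_px - 1)) {
          y <- thread_top + k
          ww <- round(wedge_w0 * (1 - k / depth_px))
          if (ww < 1) next
          cxy <- cx + slope * (y - y_mid)
          if (side == "left") {
            edge <- floor(cxy - reach)
            c0 <- max(1L, edge - ww + 1L); c1 <- max(1L, edge)
          } else {
            edge <- ceiling(cxy + reach) + 1L
            c0 <- min(W, edge); c1 <- min(W, edge + ww - 1L)
          }
          if (c1 >= c0) {
            sel <- c0:c1
            sel <- sel[!shaft[y, sel]]
            if (length(sel)) { img[y, sel] <- img[y, sel] - spec$defect_darkening; wmask[y, sel] <- TRUE }
          }
        }
        masks$wedge[[paste0(i, "_", side)]] <- wmask
      }
      half_labels <- rbind(half_labels, data.frame(
        box_id = i, side = side, label = if (damaged) "damaged" else "healthy"))
    }
  }

  ## smooth tooth-like negatives, placed clear of the implants
  placed_teeth <- 0
  tooth_id <- 0
  while (placed_teeth < spec$n_teeth) {
    ok <- FALSE
    for (try in 1:50) {
      tcx <- runif(1, 0.1 * W, 0.9 * W)
      if (all(abs(tcx - centers) >= margin_x + 0.13 * W)) { ok <- TRUE; break }
    }
    if (!ok) break
    tcy <- runif(1, 0.35 * H, 0.65 * H)
    a <- 0.10 * W; b <- 0.28 * H
    xs <- matrix(rep(seq_len(W), each = H), H, W)
    ys <- matrix(rep(seq_len(H), W), H, W)
    r2 <- ((xs - tcx) / a)^2 + ((ys - tcy) / b)^2
    bump <- pmax(0, 1 - r2)
    img <- img + 0.55 * (spec$shaft_intensity - spec$background_mean) * bump
    tooth_id <- tooth_id + 1
    tooth_boxes <- rbind(tooth_boxes, data.frame(
      id = tooth_id,
      x = max(0L, floor(tcx - a)), y = max(0L, floor(tcy - b)),
      w = min(W, ceiling(tcx + a)) - max(0L, floor(tcx - a)),
      h = min(H, ceiling(tcy + b)) - max(0L, floor(tcy - b))))
    placed_teeth <- placed_teeth + 1
  }

  structure(list(
    pixels = round(clamp8(img)),
    boxes = boxes, half_labels = half_labels, tooth_boxes = tooth_boxes,
    masks = masks, spec = spec
  ), class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("<annotated_image %dx%d, %d implant box(es), %d half label(s), %d tooth box(es)>\n",
              ncol(x$pixels), nrow(x$pixels), nrow(x$boxes), nrow(x$half_labels),
              nrow(x$tooth_boxes)))
  invisible(x)
}

#' Generate a labeled synthetic dataset
#'
#' Draws `n_images` radiographs from `spec`, overriding the defect fields so
#' that the realized fraction of damaged half-labels matches
#' `damaged_fraction` to within rounding (the damaged:healthy balance of the
#' classifier database is approximately 1:1 in the reference protocol, i.e.
#' `damaged_fraction = 0.5`). Per-image seeds are derived deterministically
#' from `seed`.
#'
#' @param spec Base [synth_spec()]; its `defect_present`/`defect_sides` are
#'   overridden per image.
#' @param n_images Number of images (>= 1).
#' @param damaged_fraction Target fraction of damaged half-labels in `[0, 1]`.
#' @param seed Master seed.
#' @return List of [generate_radiograph()] results.
#' @export
generate_dataset <- function(spec, n_images, damaged_fraction = 0.5, seed = 1) {
  stopifnot(inherits(spec, "synth_spec"))
  if (n_images < 1) stop("generate_dataset: n_images must be >= 1")
  if (damaged_fraction < 0 || damaged_fraction > 1)
    stop("generate_dataset: damaged_fraction must be in [0, 1]")
  n_halves <- n_images * spec$n_implants * 2
  n_dam <- round(damaged_fraction * n_halves)
  with_local_seed(seed, {
    flags <- rep(FALSE, n_halves)
    if (n_dam > 0) flags[sample.int(n_halves, n_dam)] <- TRUE
    seeds <- sample.int(.Machine$integer.max - 1L, n_images)
    lapply(seq_len(n_images), function(i) {
      sides <- lapply(seq_len(spec$n_implants), function(j) {
        base <- ((i - 1) * spec$n_implants + (j - 1)) * 2
        c("left", "right")[c(flags[base + 1], flags[base + 2])]
      })
      si <- spec
      si$defect_present <- any(lengths(sides) > 0)
      si$defect_sides <- sides
      si$seed <- seeds[i]
      generate_radiograph(si)
    })
  })
}

#' Write an annotated image (PNG + JSON annotations)
#'
#' Annotations follow the package's JSON dialect: one object per image with
#' `boxes` (`id, x, y, w, h`; 0-based half-open pixel boxes) and
#' `half_labels` (`box_id, side, label`).
#'
#' @param ai An `annotated_image`.
#' @param dir Output directory (created if missing).
#' @param name Basename without extension.
#' @return Invisibly, the two file paths.
#' @export
write_annotated <- function(ai, dir, name) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(name, ".png"))
  ann_path <- file.path(dir, paste0(name, ".json"))
  write_radiograph(ai$pixels, img_path)
  ann <- list(image = paste0(name, ".png"),
              boxes = ai$boxes,
              half_labels = ai$half_labels)
  if (nrow(ai$tooth_boxes)) ann$tooth_boxes <- ai$tooth_boxes
  jsonlite::write_json(ann, ann_path, auto_unbox = TRUE, digits = NA)
  invisible(c(image = img_path, annotations = ann_path))
}

#' Read annotations written by [write_annotated()]
#'
#' @param path Path to the JSON annotation file.
#' @param image_dir Directory holding the PNG (defaults to the JSON's).
#' @return An `annotated_image` (without generator masks).
#' @export
read_annotated <- function(path, image_dir = dirname(path)) {
  ann <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    pixels = read_radiograph(file.path(image_dir, ann$image)),
    boxes = as.data.frame(ann$boxes),
    half_labels = as.data.frame(ann$half_labels),
    tooth_boxes = if (!is.null(ann$tooth_boxes)) as.data.frame(ann$tooth_boxes) else
      data.frame(id = integer(0), x = integer(0), y = integer(0), w = integer(0), h = integer(0)),
    masks = NULL, spec = NULL
  ), class = "annotated_image")
}
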