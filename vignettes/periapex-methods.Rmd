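---
title: "Assessing peri-implantitis damage on periapical radiographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing peri-implantitis damage on periapical radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The clinical problem

Peri-implantitis is an inflammatory disease in which bacteria progressively
erode the alveolar bone supporting a dental implant. On a periapical film the
erosion shows as dark "subsidence" adjacent to the implant's screw threads;
the clinically decisive question is whether the bone loss has reached the
first (most coronal) thread, and it is asked separately for the mesial and
distal side of each implant. `periapex` implements a two-stage reading of
such films:

1. a grid-based convolutional **detector** locates the thread region of each
   implant;
2. each detection is **cropped**, widened horizontally, and **split** into
   two half-images along a least-squares midline;
3. each half passes through an **enhancement chain** (histogram
   equalization, adaptive equalization, difference overlay, gradient map,
   region coloring, platform reference line);
4. an AlexNet-style **classifier** labels each enhanced half *damaged* or
   *healthy*;
5. results are summarised as 2×2 confusion matrices in the
   percent-of-total table convention.

Clinical periapical film sets are generally not shareable, so the package
also ships a synthetic-radiograph generator with complete ground truth; all
quantitative statements about pipeline behaviour in this vignette are the
ones the test suite and `scripts/acceptance.R` themselves compute on that
synthetic data.

## The detector

The detector is a single-class model in the YOLOv2 mould. A
fully-convolutional backbone of seven 3×3 convolution blocks (each
convolution followed by batch normalization and leaky ReLU with slope 0.1)
downsamples a square input by a factor of 32 through five stride-2 max
pools; a sixth 2×2 pool runs at stride 1 so the resolution stays at the
grid size. A 1×1 convolution head emits, per grid cell, `n_anchors = 5`
anchor boxes with 5 values each (x/y offsets, log-width/height, objectness)
and one class score — output depth 5 × (5 + 1) = 30. With the default
416×416 input this is the canonical 13×13×30 map; `build_detector()` records
the full 34-row layer table, and the test suite audits every activation
shape in it.

Anchors are not hand-set: `train_detector()` estimates them from the
training boxes by k-means under the 1 − IoU distance (Lloyd iterations,
seeded), in grid units, sorted by area. Ground-truth boxes are assigned to
the cell containing their center and to the anchor of best width/height IoU.

The loss is the standard multi-part grid-detection sum: squared coordinate
error on responsible anchors (weight 5), squared objectness error toward 1
on responsible anchors (weight 1) and toward 0 elsewhere (weight 0.5),
except that anchors whose decoded box overlaps any truth at IoU > 0.6 are
exempt from the no-object penalty. With a single class the class-probability
term is constant and contributes nothing. Optimization is stochastic
gradient descent with momentum 0.9 at a constant learning rate; incomplete
trailing batches are discarded, so one epoch is exactly
`floor(n / batch_size)` iterations and `compute_schedule()` makes that
arithmetic explicit. No validation split is consumed during detector
training; the per-iteration loss is the only trace. Suppression of duplicate
detections (greedy NMS at IoU 0.5) is on by default but can be disabled,
which reproduces the known duplicate-detection behaviour on partially
visible implants.

All network code (convolution with groups, batch/local-response
normalization, pooling, dropout, both loss heads, the SGD-momentum loop) is
implemented in compiled code inside the package and validated in the test
suite by finite-difference gradient checks on every layer type; training is
bit-reproducible for a fixed seed because all randomness (weight
initialization, shuffling, dropout) flows from one integer seed through a
dedicated generator.

## Cropping and midline splitting

The detector's box deliberately encloses only the threaded part of the
shaft: the implant body above the threads would otherwise dominate the
image, and the damage evidence lives at the threads. Because the flanking
gingiva carries that evidence, `expand_box()` widens the box horizontally
by a configurable margin (default 20 px; clipping at the film border is
silent) before cropping.

`binarize_implant()` extracts the implant by a global Otsu threshold — the
shaft is by far the brightest structure — and keeps the largest connected
component. `fit_midline()` then regresses the column index of every
foreground pixel on its row index by ordinary least squares. An implant lies
near-vertical on a periapical film, so this is the same line one obtains by
laying the implant along the abscissa and fitting `y = β0 + β1 x`; keeping
the image upright and swapping the variable roles avoids a rotation step.
The tests verify the fit against the explicit normal-equations solution to
1e-9 relative error.

`split_halves()` assigns each pixel to the side of the midline evaluated at
its row. Conventions worth stating precisely:

* the cut at row *r* sits at `c(r) = β0 + β1 r` in column-index units; a
  pixel goes left when its center lies at or left of the cut (ties go
  left), so a vertical midline at column 50 of a 100-wide crop yields two
  50-wide halves;
* both halves are zero-padded **on their cut edge** to the width of the
  wider half, so the pair always has identical dimensions (black padding,
  matching how padded halves appear in practice);
* the split is lossless — `unsplit_halves()` reconstructs the crop
  bit-exactly, and the tests enforce this on random tilted midlines;
* mirroring the crop swaps the two halves *up to the boundary column*: the
  pixel straddling the cut must pick a side, and the left-tie rule is not
  mirror-invariant, so per row the swapped widths can differ by one pixel.
  For cuts falling between columns the swap is exact.

## The enhancement chain

The gray-level distance between gingiva and implant on raw films is small
and noisy; the chain exists to make the damaged/healthy difference visible
to a small classifier.

**Global histogram equalization.** With `p(i) = n_i / n` over `L = 256`
levels and `cdf(i) = Σ_{j≤i} p(j)`, the output is `floor(255 · cdf(in))`.
The plain `cdf × 255` scaling is used *without* the common cdf-minimum
renormalization; a consequence worth knowing is that a constant image maps
to 255 (its only occupied level has cumulative probability 1). The mapping
is monotone, and for images with many distinct values the output histogram
is uniform to within one level, both of which are tested.

**Adaptive equalization.** A contrast-limited tile-based variant written so
its degenerate case coincides with the global operator: per tile the
histogram is clipped at `clip_limit` × (tile pixel count) with the excess
redistributed uniformly, converted to a `floor(255·cdf)` mapping, and pixel
values are bilinearly interpolated between the four neighbouring tile
mappings. Defaults are an 8×8 tile grid and clip limit 0.01. With a single
tile and clip limit 1 the operator reduces exactly to global equalization
(a tested contract). Tiles smaller than 2×2 are refused;
`preprocess_half()` shrinks the tile grid automatically so tiles stay at
least 4 px on a side for small half-crops.

**Difference and overlay.** The absolute difference |HE − AHE| isolates
the structure that only local equalization reveals; it is overlaid onto the
working image by pixel-wise maximum. The subtraction's sign is not
meaningful for the downstream thresholds, which is why the absolute value
was chosen; maximum was chosen as the overlay operator because it boosts
boundaries without ever darkening the original.

**Gradient magnitude.** `sqrt(gx² + gy²)` with central differences in the
interior and one-sided differences at the borders — the height field of the
3-D edge map.

**Surface labeling.** `classify_surface()` applies, in order: a background
gate (any pixel darker than `gate_value` is background, regardless of its
neighbourhood); an edge test (local min–max range over a `range_window`
window, or the gradient magnitude, exceeding `range_threshold`); and for
the remaining flat pixels a height test (`> z_threshold` → implant, else
gum). The three thresholds default to data-driven Otsu splits computed by
`auto_surface_params()`: the range threshold from the local-range field,
the implant/gum threshold from the flat-pixel intensities, and the gate
from the flat pixels below it. All are overridable through
`surface_params()` for films where the automatic splits misbehave.

**Coloring and reference line.** Implant pixels are colored green
(0,255,0), gum orange (255,165,0), background black; edge pixels keep their
working-image gray so boundary texture survives recoloring (the reference
figures are ambiguous on this point; keeping gray preserves information the
classifier can use). One row — the implant platform, by default the top row
of the thread box mapped into half-crop coordinates, configurable via
`platform_row` — is overwritten in pure red as the damage reference line.

## The classifier

`build_classifier()` assembles the AlexNet-variant: 11×11/4 convolution
(96), ReLU, cross-channel normalization, 3×3/2 pool; 5×5 grouped
convolution (256, 2 groups), ReLU, normalization, pool; three 3×3
convolutions (384, 384 grouped, 256 grouped); pool; fully-connected 1152
and 144 with dropout (probability 0.5 — the reference architecture places
the layers but prints no value; 0.5 is the conventional choice) and a
2-way softmax head.

The input frame is 450×250×3. The tall frame suits the elongated halves:
squashing them into a square distorts the thread profile, while padding a
square frame wastes most of it. The activation arithmetic of the 450×250
frame is self-consistent through the whole chain ((450−11)/4+1 = 110,
(250−11)/4+1 = 60, … , 12×6×256 → 18432 → 1152), which is why this geometry
was adopted over a square variant; the shape audit in the test suite pins
all 25 rows. Halves are brought to the frame by aspect-preserving resize
plus symmetric zero padding (`resize_pad()`), never by stretching.

Dataset assembly follows three rules, each tested:

* **balance first** — the majority class is down-sampled to the minority
  count, so damaged:healthy is 1:1 up to one image;
* **split second** — stratified 80/20 train/validation;
* **augment last, training only** — every training image contributes its
  horizontal, vertical and combined flips (exactly ×4); validation is never
  augmented, so no flip-variant of a training image can leak into
  validation. Augmenting before the split would make the validation metric
  optimistic, and the unaugmented validation counts of the reference
  protocol support augmenting after.

Training uses softmax cross-entropy under SGD-momentum with a stepped
schedule: `rate(epoch) = initial · factor^floor((epoch−1)/period)`, default
6e-5 with factor 0.75 every 30 epochs. The default epoch budget is 50
(longer runs only refine the validation accuracy; both budgets are plain
config values).

## The synthetic generator

`generate_radiograph()` emulates exactly the statistical structure the
pipeline relies on, and nothing more:

* a textured background — white noise (sd 10 by default) plus a smooth
  low-frequency field — around a mean of 90;
* one or more bright shafts (gray 205) of configurable width, with thread
  crests rendered as alternating wider bands at the thread pitch, a plain
  collar above the first thread, and an apical taper. Crest/trough
  alternation produces the periodic edge structure the gradient map keys
  on;
* a random shaft tilt of up to ±8° — the midline-regression stage exists
  precisely because threads need not be parallel to the film's y-axis;
* optional smooth bright "tooth" blobs that act as detection negatives;
* for damaged halves, a triangular erosion wedge abutting the coronal
  threads on the chosen side: widest at the platform, tapering apically
  over `defect_depth_threads` thread pitches, darkening the adjacent
  background by `defect_darkening` gray levels (default 60; the
  desk-scale study below uses 80, a strong-contrast setting).

Placement uses the gap method (uniform over min-separated configurations),
erroring when the requested implants cannot fit. Ground truth includes the
thread-only boxes, per-half labels, and pixel masks for shaft and wedges,
which is what lets the tests measure things like "the wedge really darkens
by the configured amount" or "binarization recovers the shaft" directly
against the generator rather than against the pipeline itself.

What the generator does **not** emulate: trabecular bone texture, implant
brand geometry, exposure artefacts, overlapping anatomy, cement or crown
hardware. Passing the synthetic recovery study therefore demonstrates that
the pipeline's machinery (detection, geometry, enhancement, learning) works
end to end under the stated contrasts; it does not certify clinical
accuracy on real films, whose headline numbers require the original
(undeposited) clinical data.

## The desk-scale study conditions

The end-to-end acceptance study runs on one CPU, so it scales the networks,
not the protocol: 200 synthetic films of 160×160 px (shaft width 16, pitch
9, defect darkening 80), detector input 160 (grid 5) at width multiplier
1/8 trained 40 epochs at rate 0.002 (batch 8), classifier input 180×100 at
width multiplier 1/8 trained 20 epochs at rate 0.003 (batch 16). The
learning rates are chosen for the reduced widths — the reference rates
belong to the full-width networks — and are fixed in
`default_pipeline_config()`. 60% of the films train the detector; its
detections on the held-out 40% are cropped, split, enhanced and classified
by a model trained on the training films' truth-box halves. The suite
requires detection recall ≥ 0.9 at IoU 0.5 and held-out classification
accuracy ≥ 0.85 under these conditions, and `scripts/acceptance.R` recomputes
both from scratch at the seed the caller passes.

## Evaluation conventions

`matrix_metrics()` reports accuracy, precision, the two per-class recalls,
row subtotals and percent-of-total cells, always both raw and rounded.
Display rounding is half-up to one decimal (banker's rounding would turn
68.25 into 68.2); the raw values are retained because published tables mix
rounding conventions, and comparisons in tests use raw values. The negative
class occupies the second column ("Tooth" for detection, "Healthy" for
classification). Zero-denominator metrics are returned as `NA` and listed
in `$undefined` rather than raising. Only subtotals derivable from the
printed cells are reported; a subtotal that cannot be reproduced from its
own row or column is not invented. `render_matrix_table()` emits the
counts-with-percentages layout and `parse_matrix_table()` inverts it
losslessly.

## Numerical choices and degenerate inputs

* Equalization maps use `floor`, keeping outputs within 0–255.
* Otsu thresholds are computed on 256-level histograms; uniform inputs are
  a degenerate-threshold error (`binarize_implant` on a flat crop).
* `fit_midline` requires foreground in ≥ 2 distinct rows (rank error
  otherwise); `split_halves` errors when the midline misses the crop.
* `gradient_magnitude` requires at least 3×3, so a 1×1 half fails the
  enhancement chain with a stage error, by design.
* Pixels exactly on the midline go left; the mirror asymmetry this causes
  is at most one column per row (see above).
* Batch normalization uses batch statistics in training and running
  averages (momentum 0.1) at inference; ties in max-pooling resolve to the
  first maximum in scan order.

## Known limitations

* The synthetic study bounds what desk-scale evidence can show about
  clinical films (see above); the clinical headline accuracies are not
  reproducible without the original data.
* Halves are named left/right, not mesial/distal: anatomical naming needs
  the tooth quadrant and film orientation, which the inputs do not encode.
* The detector trains from scratch; no transfer learning.
* Multi-class dental detection, ROC analysis and cone-beam CT are out of
  scope.
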