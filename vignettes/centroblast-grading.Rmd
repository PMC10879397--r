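---
title: "Methods: centroblast detection scaffolding and WHO grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: centroblast detection scaffolding and WHO grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbdetect)
```

## Scope and model

Follicular lymphoma is graded from the density of centroblasts (CBs):
the WHO bands are grade I for 0–5 CBs per high-power field (HPF), II for
6–15, III for more than 15, with the count conventionally averaged over 10
HPFs. `cbdetect` implements everything *around* a CB detector — candidate
geometry, background removal, detection metrics, hard-negative mining,
dataset bookkeeping, grading — while the detector itself is pluggable:
either YOLO-format prediction files from a trained model, or the built-in
classical baseline. This mirrors the design of the detection pipelines used
in this area, where the deep model is swapped and retrained freely but the
surrounding measurement machinery must stay fixed and auditable.

Assumptions inherited from that setting:

* patches are axis-aligned crops of a WSI at native resolution
  (0.12 µm/px by default), cells dark on a light background;
* one box per cell, boxes axis-aligned, in the normalized YOLO frame;
* class 0 is "CB", class 1 is "non-CB" (mined hard negatives).

## The candidate-cell geometry

A segmented cell is a candidate CB when

* its **equivalent circular diameter** `2·sqrt(area/π)·umpp` is at least
  **5.13 µm** (CBs are large), and
* its **aspect ratio** lies in **[0.7, 1.3]** (CBs are approximately
  round).

The aspect ratio is the ratio of the two side lengths of the minimum-area
rotated bounding rectangle of the contour, *in fitted order, not sorted*.
A strict major/minor ratio is ≥ 1 by construction, which would make the
lower half of a symmetric 0.7–1.3 band unreachable; taking the sides in
fitted order makes the band meaningful in both directions, and a decision
under the symmetric band is identical either way. The rectangle is fitted
with rotating calipers on the convex hull of the component's pixels, with
each extent padded by one pixel so that an axis-aligned block of w×h pixel
centers measures w×h.

Contours touching the patch border are kept: a CB straddling two tiles is
still counted in the tile holding its centroid. Raw component pixels (not
convex hulls) feed the area computation.

The built-in baseline detector emits the axis-aligned bounding box of each
surviving contour with confidence `clamp(d_um / (2 × 5.13), 0, 1)` —
monotone in cell size, 0.5 exactly at the diameter threshold. It is a
stand-in, deliberately simple; it exists so the full pipeline, including
evaluation and mining, runs deterministically without trained weights.

## Background removal

The preprocessing arm whitens everything that is not a cell:

1. histogram-equalize the patch;
2. convert to grayscale;
3. Otsu-threshold (foreground = darker side);
4. detect contours (8-connected components);
5. average the areas of their axis-aligned bounding rectangles, `A`;
6. dilate the binary mask;
7. fill solid the interior of every contour whose area is below
   `fill_ratio × A` (default 0.5);
8. keep the original pixel values under the mask, set the rest to
   (255, 255, 255).

Numerical and interpretation choices:

* **Equalization channel.** Equalization acts on 8-bit luminance
  (Rec. 601 weights) with the standard `(cdf − cdf_min)/(N − cdf_min)`
  mapping, and the RGB channels are rescaled multiplicatively. Per-channel
  equalization would shift hue, which matters when stain color itself
  carries meaning (purple fresh H&E vs pink faded slides). A
  constant-luminance patch is a degenerate histogram and is returned
  unchanged.
* **Dilation kernel.** Disc, radius 2 px, one pass, configurable — the
  procedure names the operation but no kernel; radius 2 at 0.12 µm/px is a
  0.24 µm halo, enough to reconnect a thin rim without merging neighbors.
* **Step 5 vs step 7 areas.** The average in step 5 is of *bounding
  rectangle* areas while the comparison in step 7 uses the *contour* (pixel)
  area — the literal reading of the procedure's mixed wording. Since a
  component's pixel area is at most its rectangle area, this errs toward
  filling slightly more small contours, which is the conservative direction
  (filling only ever keeps pixels).
* **"Fill in" small contours** is implemented as filling the enclosed holes
  of those components (4-connected background not reachable from the patch
  border), i.e. solidifying ring-like nuclei.
* **Degenerate Otsu** (single-valued histogram) returns the input unchanged
  with a message.
* An alternative `mode = "mean_white"` whitens every pixel brighter than
  the patch's mean luminance. The upstream description of the preprocessing
  exists in two inconsistent versions — the contour algorithm above and a
  mean-color white-out; the package implements the algorithmic version as
  the default and exposes the mean-color variant rather than guessing which
  produced the published figures. The terms "histogram normalization" and
  "histogram equalization" in that description are treated as synonyms.

Two properties are enforced by tests rather than assumed: every output
pixel is either its original value or pure white, and a second pass can
only whiten further (it never restores pixels).

## Detection metrics

Matching is per image, per class, greedy in descending confidence,
one-to-one: each detection claims the unmatched ground truth of highest
IoU if that IoU reaches the threshold, otherwise it is a false positive;
ties in confidence are broken by input order so results are reproducible.
AP uses all-point interpolation — the area under the precision envelope of
the PR staircase. The upstream prose describes AP loosely as "average
precision over confidence thresholds"; the tooling it builds on uses
continuous interpolation, and that convention is adopted here. mAP over
the ladder 0.50–0.95 (step 0.05) is the arithmetic mean of the
per-threshold values; with one class the per-threshold mAP equals that
class's AP. Edge conventions: no ground truth and no detections gives
precision = recall = 1; detections without ground truth flag recall as
undefined; a class absent from the ground truth is excluded from the
class average.

The test suite pins the kernel to an independent brute-force oracle
(re-matching from scratch at every distinct confidence cut, exact staircase
integration) on 1,000 randomized instances, plus a hand-worked
3-detection example (AP = 1/2 + 1/2·2/3 = 0.8333…).

## Hard-negative mining

False positives of a fixed detector, at IoU threshold 0.5 against the CB
ground truth, become class-1 "non-CB" labels. Three controls mirror the
stated intent of keeping negatives comparable in number and shape to the
positives:

* **size band** — a negative's width and height must fall inside the
  5th–95th percentile band of ground-truth CB box sizes ("shape
  similarity" operationalized as a size band, since no explicit rule is
  given);
* **global cap** — at most `cap_ratio` (default 1.0) × the total CB count,
  applied globally rather than per image, matching the global phrasing of
  the constraint;
* **priority** — descending confidence: the most confident mistakes are
  the hardest negatives.

Building the two-class dataset never modifies CB boxes, drops any negative
that overlaps a CB at IoU ≥ 0.5 (it would contradict its false-positive
status), and skips negatives already present, making the whole pass
idempotent against a fixed detection set. Negatives appear in whichever
partition their image belongs to, so mining runs per partition.

## Dataset splitting and accounting

The split carves test off first, `ceil(test_frac · n)`, then divides the
remainder `ceil((1 − train_frac) · rest)` into validation and the rest into
training. This ceiling convention is the only one of the four
floor/ceiling combinations that maps 1,205 images at 5% / 80–20 onto
915 / 229 / 61 — the package's worked accounting example. Membership is a
seeded shuffle of the sorted ids, so the split is a permutation-invariant
function of (ids, seed). An optional grouping key (e.g. patient or slide)
moves whole groups between partitions; the default is per-image splitting,
which is what the worked example implies, but per-slide grouping is the
right choice when leakage across a patient's patches matters.

## Grading

`who_grade()` applies the bands I: [0, 5], II: (5, 15], III: (15, ∞) to a
real-valued count; fractional means are compared directly to the edges
(a mean of 5.4 → II) since the source scheme speaks in integers and states
no rounding rule. `grade_slide()` averages the supplied per-HPF counts and
warns (not fails) when the field count differs from the conventional 10.
A detection-derived count is the number of class-0 detections at a
confidence cut of 0.25, the customary reporting default of the
interoperating detection tooling.

**Caveat on HPF size**: one 512-px patch at 0.12 µm/px is a 61.4 µm
square, far smaller than a conventional microscope HPF, and the upstream
description never fixes the HPF area relative to its patches. The
patch-to-HPF aggregation factor (`patches_per_hpf`) is therefore explicit
configuration, default 1 patch = 1 counting unit. Grades derived from
patch counts are *not* WHO grades unless that factor is calibrated to the
microscope's field.

## The synthetic world

The generator renders filled rotated ellipses over a textured light
background and is the package's substitute for slide data:

* **palettes** — purple (background ≈ RGB 231/218/236, cells ≈ 118/62/150)
  for fresh hematoxylin-rich slides; pink (247/228/233, 205/110/140) for
  aged slides where hematoxylin has faded. Anchors are package constants
  chosen to give cell/background luminance contrast well above 60 levels;
  no colorimetry was published to match.
* **populations** — CBs: equivalent diameter uniform on 7–10 µm, axis
  ratio ≤ 1.25 (comfortably above both filter thresholds); clutter: small
  round cells 2.5–4.5 µm or elongated cells of ratio 2–3 (each clearly on
  the reject side of one criterion). The margin to the 5.13 µm / 0.7–1.3
  thresholds is deliberate: it makes verdict truth unambiguous under
  rasterization so the closed-loop filter test can demand exactness.
* **background texture** — a low-frequency multiplicative field
  (amplitude 0.04) so Otsu never sees a trivially uniform background;
  optional additive Gaussian pixel noise (default sd 3 levels).
* **ground truth** — each CB's box is the exact bounding box of its
  rasterized pixel set; the generator is a pure function of its spec
  including the seed (byte-identical reruns).
* **placement** — rejection sampling with whole-scene restarts keeps cells
  disjoint (center distance > sum of semi-major axes + 4 px) when overlap
  is disallowed; infeasible packings error out rather than silently
  overlap.

What a green closed-loop test does establish: the geometry, metric and
masking code paths are exact on scenes whose truth is known. What it does
not establish: performance on real H&E tissue — no chromatin texture, no
touching or overlapping nuclei, no stain variation beyond the two-palette
toggle, no out-of-focus regions. The generator is a correctness instrument,
not a realism instrument.

## Known limitations

* The deep components this scaffolding was designed around (cell
  segmentation, the trained detector) are out of scope by design; the
  classical stand-ins are much weaker on real tissue.
* Published benchmark metrics of the upstream pipeline are not
  reproducible without its private slides and weights; the package's
  quantitative guarantees are its worked examples and property suites.
* Only PNG rasters are read (no pyramidal WSI containers, no TIFF in the
  offline environment); tile from pre-extracted images.
* Edge tiles are dropped, not padded — evaluation is defined on full-size
  patches only.
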