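---
title: "Annotation quality control for COCO polygon datasets: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation quality control for COCO polygon datasets: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyqc)
```

## Why screen annotations at all

Instance-segmentation training sets in medical imaging are annotated by
hand, frame by frame, as polygons in COCO JSON. A fraction of those
polygons is structurally broken in ways that numerical training metrics
never surface directly: empty segmentation lists, truncated vertex runs,
coordinates outside the frame, shapes that collapse to (near) zero area,
and boundaries that cross themselves so "inside" is ill-defined. A second
population is geometrically well-formed but tiny — stray specks from
boundary artifacts or slips of the annotation tool — which add label noise
out of proportion to their pixel count. polyqc screens for the first
population, rasterizes the survivors to native-resolution binary masks,
removes the second population by pixel-area threshold, and accounts for
every annotation so the refinement is fully auditable.

## The validation screen

Each annotation is checked in a fixed order, and the verdict records the
*first* failing check:

1. `INVALID_EMPTY` — segmentation key missing or an empty list;
2. `UNSUPPORTED_RLE` — run-length-encoded or `iscrowd` masks (this
   pipeline is polygon-based; silently rasterizing RLE would corrupt the
   area statistics, so these are rejected with their own code);
3. `INVALID_ODD_COORDS` — a flat coordinate list of odd length cannot be
   paired into vertices;
4. `INVALID_TOO_FEW_VERTICES` — fewer than three vertices after dropping a
   duplicated closing vertex (some export dialects repeat the first vertex
   to close the ring; counting it would misclassify closed triangles);
5. `INVALID_OUT_OF_BOUNDS` — any vertex with `x < 0`, `y < 0`,
   `x > width` or `y > height`. Coordinates exactly on the image extent
   pass (COCO permits them); `bounds_tolerance` (default 0 px) can admit
   small excursions;
6. `INVALID_DEGENERATE_AREA` — analytic (shoelace) area below `epsilon`,
   default 1 px². "Near zero" needs a number: a sub-pixel polygon cannot
   rasterize to a meaningful mask, so one pixel is the natural floor. The
   shoelace area is used here, not the rasterized one, because degenerate
   shapes are exactly the ones a rasterizer handles unpredictably;
7. `INVALID_SELF_INTERSECTING` — two non-adjacent edges properly cross, or
   a vertex lies strictly in the interior of a non-incident edge. Edge
   pairs sharing an endpoint never count, nor does vertex-vertex contact,
   so legal ring closures are not flagged. The test is exact all-pairs
   O(n²), ample at annotation-polygon sizes. This check participates in
   the default screen but can be switched off
   (`check_self_intersection = FALSE`) for pipelines that only apply the
   four structural criteria.

Ordering is cheapest-and-most-structural first. It matters for reporting:
a symmetric bow-tie has zero shoelace area and is therefore counted as
degenerate, not self-intersecting. Multi-part annotations are strict: one
bad part invalidates the instance, matching removal accounting done per
instance rather than per part. Repair (re-winding, self-union,
simplification) is deliberately out of scope — invalid polygons are
removed, not fixed.

## Rasterization conventions

Masks are generated at the native image resolution so they stay
pixel-aligned with the source frames. A pixel at column `c`, row `r`
(0-based) is set iff its center `(c + 0.5, r + 0.5)` is inside the polygon
under the even-odd rule. Centers exactly on an edge follow a top-left
rule, implemented as half-open spans on both axes: the top edge of an
interior is inside, the bottom edge is not; the left end of a span is
inside, the right end is not. Two consequences make this the right
convention for QC work: adjacent polygons never double-count a boundary
pixel, and an axis-aligned rectangle covers exactly the pixels whose
centers it contains (a 3×3-px rectangle has pixel area 9, regardless of
position). Multi-part instances rasterize to the pixel-wise union of
their parts.

The filter area is the *rasterized* pixel count, not the shoelace area:
the threshold is meant to suppress what the mask actually contributes to
training, and for thin or concave shapes the two can differ. For convex
polygons the difference is bounded by roughly the perimeter in pixels,
a property the test suite asserts on random polygons.

Foreground connectivity is 8-connected (diagonal contact joins), so thin
diagonal structures are not spuriously split into fragments; this is
implemented as a union-find pass because the otherwise-natural
`EBImage::bwlabel` labels 4-connected components.

## Area filtering and its threshold

`apply_area_filter()` removes instances with `pixel_area < threshold` —
strictly below, so an instance exactly at the threshold survives. The
default threshold is 700 px² with a default sensitivity grid of
300/500/700/1000 px². The threshold is a property of the dataset, not of
the model: `sensitivity_analysis()` supports choosing it by distributional
inspection (how many instances each candidate removes) before any
training, and the package deliberately offers no machinery to tune it
against downstream model metrics. Every sensitivity table carries the size
of the population it was computed on, because removal percentages are
meaningless without it — and published tables do not always state theirs.

`area_statistics()` summarizes the (typically strongly right-skewed) area
distribution with mean, median, a log10-scale histogram, and the 2nd
percentile, a useful anchor when picking a noise floor. Percentiles use
linear interpolation between closest ranks (quantile type 7), stated
explicitly so figures derived from it can be cross-checked against other
software.

The accounting in `build_qc_report()` enforces conservation: the filter
only ever sees annotations that passed validation, the two removal classes
are disjoint, and `raw == removed_invalid + removed_small + retained` on
the totals and within every split. Violations are errors, not warnings.

## Overlay review

`render_overlay()` alpha-blends a mask over the frame
(`out = (1 − α)·image + α·color` per channel, rounded half away from
zero), default pure red at α = 0.4 — opaque enough to judge boundary
fidelity, transparent enough to see the anatomy under it. Rendering is
pixel-exactly reproducible, and the settings travel with the output so
overlays from different runs are comparable. `flag_instances()` automates
the two overlay-level error categories that are computable — fragmented
masks (≥ 2 components) and isolated small components within them — as
*advisory* flags for the reviewer; misalignment against anatomy, the third
category, requires a human eye and is exactly what the rendered overlays
are for.

## YOLO export

The cleaned dataset exports to the conventional YOLO segmentation layout
(`images/{train,val}`, `labels/{train,val}`, `data.yaml`). Label lines are
`class x1 y1 x2 y2 ...` with coordinates normalized by image width/height,
clamped to [0, 1] and printed at 6 decimals (≈ 10⁻⁴ of typical image
sizes, which the round-trip test bounds). Class indices are the rank of
the COCO category id in ascending order. Multi-part instances are written
one line per part — the lossless choice, since the format has no
multi-polygon instance — and the export summary records that policy.
Splits are image-level and leakage is a hard error at export time, not a
warning; a seeded `random_split()` exists for synthetic data, while
datasets with a published split should use it as-is.

## Dice and the paired Wilcoxon test

Frame-level DSC unions all instance masks of a frame (class-agnostic)
before computing `2|A∩B|/(|A|+|B|)`; per-class evaluation is the same
call on per-class mask subsets. Two empty frames score 1.0 by convention
— both raters agree there is nothing to segment — and the convention is a
parameter (`empty_value`) because the alternative (`NA`, dropping such
frames) is also defensible.

`wilcoxon_signed_rank()` discards zero differences, average-ranks ties,
and reports W⁺ with a two-sided p. Up to 25 effective pairs the p-value is
exact: the null distribution of W⁺ over all 2ⁿ sign assignments is
computed by generating-function convolution over the doubled
(tie-averaged) ranks — identical to complete enumeration, valid under
ties, and O(n · Σr) instead of O(2ⁿ). Beyond 25 pairs a normal
approximation with tie and continuity corrections takes over; at the
boundary the two agree to well under 0.02, which the suite asserts. When
every difference is zero the result is flagged degenerate with an `NA`
p-value rather than raising an error, so batch comparisons do not fall
over on an identical pair.

## The synthetic-data generator

`generate_dataset()` produces a COCO dataset plus a manifest recording the
injected class of every annotation id. Defaults: 12 images at 320×320 px,
2 well-formed instances per image, 3/2/2/2/2 instances of the five defect
classes, 3 valid-but-small instances, 9 categories, and a 700 px²
boundary between small (< 700) and valid (900–6000 px²) rasterized areas.
This composition mirrors a curated endoscopy annotation set — roughly a
third of raw annotations structurally defective and a small sub-threshold
tail — with the defect share on the conservative side, and nine categories
matching an airway-landmark class inventory.

Construction guarantees each class exhibits its defining defect and no
other, so first-failure ordering cannot blur manifest counts: valid and
small instances are convex (vertices on a random ellipse,
rejection-sampled until the rasterized area lands in the target range);
out-of-bounds instances are valid shapes shifted partly out of frame;
degenerate ones are collinear triplets or sub-pixel squares;
self-intersecting ones are crossed quadrilaterals with *unequal* lobes,
whose shoelace area is well above `epsilon` (a symmetric bow-tie would be
claimed by the degeneracy check first). A single RNG stream per call,
seeded from the spec and restored afterwards, makes generation
byte-reproducible without touching the caller's RNG state.
`generate_mask_pair()` builds equal-area mask pairs as row-major pixel
runs, which is what makes the intersection exactly
`round(f · block_area)` for every fraction — the analytic DSC oracle used
throughout the statistics tests.

What the generator does not emulate: photorealistic endoscopy (textures,
specular highlights, blur), anatomical shape priors, annotator-specific
boundary style, or inter-annotator disagreement. Green tests therefore
demonstrate that the *mechanics* — screening, rasterization, accounting,
export, statistics — are exact on data whose ground truth is known by
construction; they do not certify that any particular threshold or screen
is clinically appropriate for a new dataset, which remains a judgment made
with the sensitivity table and the overlays.

## Problem sizes and numerical notes

The shipped test suite checks the manifest-recovery property on 50 random
generator specifications (160×160 px images), the self-intersection
predicate against an independently written parametric-line oracle on
1,000 random grid polygons of up to 12 vertices, rasterized areas against
a per-pixel point-in-polygon oracle on hundreds of random convex polygons,
and the exact Wilcoxon p against literal 2ⁿ enumeration for all n ≤ 10 —
sizes at which the oracles are unarguable and the whole suite runs in
well under a minute. Geometry tests use integer vertex coordinates so both
implementation and oracle are exact; boundary-tie behavior in
rasterization is pinned by the rectangle cases instead, where the
convention is decidable in closed form.

Known limitations: the out-of-bounds rule is all-or-nothing per instance
(no clipping); RLE masks are rejected rather than converted; exact
reproduction of another pipeline's pixel areas can differ by boundary
pixels if that pipeline's rasterizer uses a different tie rule; and the
area threshold, validated here on one kind of data composition, should be
re-derived from the area distribution for datasets with different
annotation characteristics.
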