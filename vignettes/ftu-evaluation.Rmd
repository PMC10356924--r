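---
title: "Evaluating FTU instance segmentations: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating FTU instance segmentations: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftuseg)
```

## Why object-level evaluation

Segmentation models for histopathology emit one foreground mask per
whole-slide image. Two models with near-identical pixel Dice can
differ wildly in how many functional tissue units (FTUs) they actually
delineate: a mask that fuses five adjacent glomeruli into one blob
loses almost no pixels but four objects. `ftuseg` therefore evaluates
at two levels and keeps them distinct throughout:

* **pixel Dice** of the union masks per WSI — the leaderboard
  semantics under which predictions are usually ranked, including the
  rule that a WSI with no prediction at all enters the mean as a zero;
* **object-level confusion counts** after instance separation and
  one-to-one matching — the semantics under which precision and recall
  per FTU are defined.

Both are reported by `wsi_metrics()`; neither stands in for the other.

## The evaluation model

### Instance separation

Predictions arrive as a single binary mask (run-length encoded, in the
1-based column-major dialect of the hosting platform — the encoding
itself is standard, its pixel ordering is a platform convention that we
document rather than can derive). Adjacent FTUs merge into one
connected component, so the mask is separated by marker-controlled
watershed:

1. Euclidean distance transform of the foreground (`EBImage::distmap`);
2. local maxima of the distance map, with no two markers closer than
   the **minimum distance** parameter — the one tunable of the step;
3. flooding of the negated distance map from the markers, restricted
   to the foreground, so that the foreground pixel set is preserved
   exactly.

The minimum distance is exposed as named presets (`kidney-hubmap` =
30 px, `colon-hubmap` = 60 px, `hpa` = 80 px), matching the values
used with the datasets this package models. Geometrically the
parameter must sit between the typical object radius and the typical
center-to-center spacing: below the radius, a single elongated object
(or even the distance ridge of a bridge between objects) can seed a
second marker; above the spacing, true neighbors collapse into one.

Three determinism choices are deliberate, since reproducible labelings
are a prerequisite for regression testing: maxima ties are broken in
row-major scan order; a connected plateau of equal distance values
contributes one marker at its highest, then first, pixel; the flood
processes pixels in decreasing distance with FIFO tie-breaking.
Connected components that end up with no marker (possible when
suppression removes a small object's only peak) keep their own labels
rather than disappearing. Labels are finally renumbered 1..K in
row-major first-encounter order.

The manual alternative — split lines drawn between merged objects — is
implemented as `apply_split_lines()`: the 1-px rasterized polylines
are cleared to background *before* component labeling, mirroring the
manual-correction workflow. The cleared pixels (≈ 1 px of area per
cut) are consequently excluded from per-instance Dice.

### Matching

Candidate pairs are (ground truth, prediction) instances sharing at
least one pixel, accepted greedily in descending pairwise-Dice order,
one-to-one, with ties broken by ascending label pair. Accepted pairs
with Dice ≥ 0.5 (the conventional threshold, tunable) are TP;
unmatched or sub-threshold predictions are FP; unmatched ground truths
are FN. Greedy matching is the standard deterministic choice for
object-level F-scores; an optimal assignment differs only on contrived
ties. Two useful properties follow directly: every instance appears in
exactly one row of the match table, and raising the threshold can
never increase the TP count.

A sub-threshold accepted pair produces an FN row and an FP row that
both carry the achieved pairwise Dice; instances with no overlap at
all carry 0. The mean per-instance Dice of a WSI is the mean over all
rows under that convention.

### Degenerate inputs

Empty-vs-empty masks have Dice and Jaccard 1 by convention, and this
propagates: with neither predictions nor ground truth, precision and
recall are reported as 1 (with only one side empty, 0). The Matthews
correlation coefficient returns 0 whenever a denominator factor
vanishes. Hausdorff distance on an empty point set is an error, not a
sentinel value.

## Density

Per WSI, `ftu_density()` reports the FTU count, the mean FTU polygon
area — shoelace area in px², converted to µm² by multiplying with the
squared pixel size — and the cortex area in mm² as the **sum** of the
individual cortex polygon areas. The sum, not the union: overlapping
cortex polygons double-count. This reproduces the conventional
computation for these datasets; a `cortex_union = TRUE` option
rasterizes and unions instead for users who prefer the
geometrically-correct area. Density is the count divided by the cortex
area; zero cortex is an error rather than an infinite density. FTU
counting uses the annotation count with no size filtering. Printed-style
outputs round half away from zero (`round_half_up()`), matching how
such tables are typeset, e.g. 80 498 px × (0.5 µm)² = 20 124.5 µm² →
20 125.

## The synthetic generator

`generate_scene()` emulates the *geometry* of the source imagery, not
its appearance: glomeruli are quasi-ellipses with axis ratio in
[0.8, 1] (they are roughly spherical in tissue) and 2 % radial
harmonic noise, diameters drawn uniformly from 100–350 µm; crypts are
elongated ellipses with a normal(73.5, 3.4) µm cross-section and an
axis ratio of ~0.17 (≈ 433 µm length). Instances are packed by
rejection sampling into a cortex band covering 55 % of the canvas,
with a minimum boundary gap of 2 px; an unplaceable request raises a
capacity error instead of silently under-filling. The label mask is
the rasterization of the instance polygons, so the two truth
representations agree exactly by construction.

The default canvas is 2048 × 2048 px at 4 µm/px — a "downscaled WSI"
on which a glomerulus spans 25–88 px — because the evaluation logic is
scale-free and desk-scale scenes keep the test suite fast; the native
0.5 µm/px resolution is supported but not default. Tests use smaller
canvases still (typically 400–512 px); the oracle suite runs 100
scenes of 3–6 instances at 512 × 512, and the cohort checks use
4 donors × 2 scenes at 512 × 512 and 8 µm/px. All sizes are package
choices made for fast, deterministic suites.

All randomness flows from one mandatory seed through per-subtask
derived streams (shapes, placement, each perturbation), so enabling a
perturbation does not shift the draws of another.

`perturb()` plants a known evaluation outcome: `drop_n` instances are
removed (the FNs), `add_n` disjoint blobs added (the FPs),
`merge_pairs` nearest pairs bridged by a 3-px neck (restored by
watershed separation), and boundaries dilated/eroded by `jitter_px`.
The expected counts `(tp, fp, fn) = (n − drop, add, drop)` are exact
whenever jitter leaves every surviving pairwise Dice at or above the
matching threshold — for the default geometry a 2-px jitter keeps
Dice ≈ 0.85, far above 0.5.

`generate_cohort()` plants a per-donor density drawn uniformly from
3–6 FTUs/mm² (a plausible sectional glomerular density for human
cortex) and sets each scene's instance count to
`round(density × cortex area)`; the recovered density therefore
matches the planted one up to that rounding, below 2 % at the default
cohort scene size.

### What passing tests do and do not show

The generator validates the *bookkeeping*: codecs, separation,
matching, tallies, density arithmetic. It does not emulate stain
texture, sclerotic or otherwise ambiguous FTUs, annotation noise,
irregular cortex geometry, or the failure modes of learned models —
scores on real WSIs depend on all of these. A perfect oracle suite
says the pipeline measures correctly, not that any segmentation model
is good.

## Numerical choices

* Rasterization sets a pixel iff its center lies inside the polygon
  (even-odd rule; boundary-center ties count as inside): deterministic,
  resolution-consistent, and monotone under polygon containment.
  Interior rings are subtracted by the same rule.
* `vectorize()` traces label boundaries along pixel *edges* (crack
  following), so rasterizing the polygon reproduces the label exactly
  for solid 4-connected blobs; interior holes are filled, which is why
  the round-trip guarantee is stated for blobs.
* Annotation JSON is written with 17 significant digits so coordinate
  round-trips are bit-exact.
* Label TIFFs use 16-bit unsigned samples: real WSIs carry thousands
  of instances, so 8 bits would overflow.
* Connected-component labeling, the watershed flood, polygon filling
  and boundary tracing are small C++ routines: the labeling and flood
  need explicit connectivity and deterministic orders that
  tolerance-based watershed implementations do not expose, and the
  fill/trace pair must be exact inverses of each other.

## Known limitations

* Watershed with a single global minimum distance cannot separate all
  shapes; strongly varying object sizes in one image (typical for
  crypts) need per-dataset tuning, and genuinely complex structures
  are better served by learned instance segmentation — outside this
  package's scope.
* Greedy matching is not an optimal assignment; with pathological tie
  structures a different pairing could alter counts by one.
* The summed cortex area deliberately double-counts overlaps (see
  above).
* The generator's capacity errors appear well below theoretical
  packing density because placement is rejection sampling, not an
  arrangement algorithm.
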