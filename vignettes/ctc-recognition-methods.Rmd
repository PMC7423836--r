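---
title: "Recognizing circulating tumor cells in imFISH fields: methods and design"
author: "ctcscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing circulating tumor cells in imFISH fields: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcscope)
```

## The measurement problem

Circulating tumor cells (CTCs) are enumerated from blood after leukocyte
depletion by combined immunofluorescence and FISH (imFISH). Each microscopy
field carries four aligned channels: DAPI (nuclei), CD45 (pan-leukocyte
antigen), and the centromere enumeration probes CEP8 and CEP17. A nucleated
event is scored a CTC when it is a clean single nucleus, DAPI-positive,
CD45-negative, and hyperdiploid — three or more probe signal points — on
chromosome 8 or 17. Scoring by eye is slow and subjective; `ctcscope`
implements the scoring standard as an algorithm (the *rule-based caller*)
and also trains an AlexNet-style CNN on per-nucleus crops as an
alternative recognizer, with a synthetic field simulator supplying ground
truth for both.

## The rule-based caller

### Nucleus segmentation

Nuclei are segmented on the DAPI channel: Gaussian smoothing
(`smoothing_sigma_px`, default 2 px), Otsu binarization, then morphological
cleaning — opening with a disc of `morphology_radius_px` (default 5 px),
hole filling, closing with the same disc, and removal of components below
`min_area_px`. The Otsu threshold maximizes between-class variance over all
integer thresholds; foreground is *strictly above* the threshold, ties
break toward the lower threshold, and a single-valued image yields an empty
foreground rather than an arbitrary split. A Sobel gradient-magnitude
operator (3x3 kernels, reflective borders) is provided and exposed, but the
threshold-plus-morphology path is the decisive one: it directly produces
the filled nucleus masks that the downstream per-nucleus measurements need,
whereas edge maps would require an additional contour-closing stage.

Each 8-connected component becomes a nucleus region, labeled in raster-scan
order of its topmost-leftmost pixel, with area, centroid, bounding box and
solidity (area over convex-hull area). Quality-control flags implement the
exclusion condition of the scoring standard: `TOO_SMALL`/`TOO_LARGE` from
the area gates, `AGGREGATED` when solidity falls below `min_solidity`
(default 0.85 — a fused pair of nuclei forms a dumbbell with visibly lower
solidity, while a single convex nucleus sits near 0.97), and
`TOUCHES_BORDER` for clipped nuclei. Flagged regions are retained in the
output but classified `EXCLUDED`. The scoring standard names no numeric
thresholds for exclusion, so the defaults here are engineering choices,
stated once and configurable.

Area gates default to 200–50 000 px at the native acquisition scale of
2728 x 2192 and scale linearly with field area for smaller fields. The
scaled maximum gate is floored at 3000 px: a small crop or mini-field still
holds a full-size nucleus, and a strictly proportional gate would reject
every nucleus in it.

### The watershed baseline

A marker-controlled watershed is provided for comparison: Otsu
binarization, opening and hole filling, then the Euclidean distance
transform flooded from its regional maxima (minimum peak separation equal
to `morphology_radius_px`). Touching nuclei are split along watershed
lines. The closing step of the primary path is deliberately omitted here:
closing fattens the neck between two fused nuclei, which raises the
distance-map saddle toward the smaller lobe's peak and erases exactly the
feature the watershed segments on. Overlaps much deeper than about 20% of
a radius leave no saddle at all, and no distance-based watershed can
separate them; that regime is the `AGGREGATED` flag's job, not the
watershed's.

### CD45 gating (the red proportion)

The scoring standard calls a nucleus a common leukocyte when "the
proportion of red" over the nucleus footprint exceeds 30%. The standard
does not define the proportion at pixel level, so the caller defines it as
the fraction of nucleus-mask pixels whose CD45 intensity exceeds a global
positivity threshold — Otsu over the whole CD45 channel by default, or a
fixed intensity via `caller_params()`. Two details matter:

* **Boundary reading.** "Higher than 30%" is strict: a red proportion of
  exactly 0.30 still passes the gate. The boundary is tested.
* **Weak-signal guard.** On a field with no genuine CD45 staining the
  channel is noise; Otsu would split the noise and mark roughly half of
  every nucleus "red". A threshold in the bottom tenth of the bit range
  cannot correspond to antibody signal, so the caller falls back to half
  the bit range, making the red proportion of unstained fields 0 rather
  than an artifact of noise splitting.

### FISH spot counting and the merge rule

Within each nucleus mask dilated by `margin_px` (default 5 px, so rim
signals are kept), a white top-hat filter with a disc of
`max_spot_radius_px` (default 8 px, consistent with CTC image features
being no larger than about 10 px) isolates compact bright features; the
top-hat response restricted to the region is Otsu-thresholded and
8-connected components of at least `min_spot_area_px` (default 4 px)
become signal points.

The scoring standard merges two signal points closer than "the diameter of
one point". For unequal spots that phrase is ambiguous; the caller reads it
as the mean of the two equivalent diameters (`min` and `max` are exposed as
alternatives). Merging is transitive — connected components of the
closer-than-one-diameter graph collapse to single points with summed area
and area-weighted centroid — because sequential pairwise merging would
depend on input order. A collapsed point has a larger diameter than its
members, so the collapse is iterated to a fixed point; this makes the
operation idempotent and permutation-invariant, which the test suite
checks against a brute-force oracle.

A probe channel absent from the field yields an *unavailable* count
(`NA`), never 0: a missing probe must not silently read as diploid.

### Classification

`classify_nucleus()` applies the four conditions in order and records each
outcome in a `reasons` trace: (1) any QC flag excludes the nucleus; (2)
DAPI positivity is satisfied by construction for DAPI-segmented nuclei and
recorded explicitly; (3) red proportion at most the cutoff; (4) the signal
logic over available CEP8/CEP17 counts reaches `min_signal_points`
(default 3). The "CEP-8+/CEP-17+" slash is read as OR — hyperdiploidy of
either chromosome suffices, the convention of dual-probe imFISH panels —
with AND available by configuration. An unavailable count fails its
condition; with OR logic and both probes unavailable the call is negative
with the reason recorded. The caller is a pure function: calls are
monotone in the gates (raising the red proportion can only demote, adding
a signal point can only promote), which is tested property-style.

## The CNN alternative

The classifier is an AlexNet-style network with eight weighted layers:
five "same" convolution layers (max-pooling after layers 1, 2 and 5) and
three fully connected layers ending in a 2-way softmax over CTC /
non-CTC. A 1000-way head would be the ImageNet configuration and
contradicts the binary task, so the head is 2-way. Input is the
per-channel crop stack (DAPI, CD45, CEP8, CEP17 planes — lossless, unlike
a color composite), cropped at 1.5x the nucleus bounding box, reflectively
padded, and resized to `input_size` (default 64 px at desk scale).

The searched hyper-parameters mirror the model's tuning grid: activation
in {softmax, ReLU, tanh}, kernel regularizer in {l1, l2} on the fully
connected layers, factor in {0.01, 0.02} — twelve cells under stratified
5-fold cross-validation with seeded folds, ties broken in grid order.
"Softmax" as a *hidden* activation is unusual but implemented literally
(per-position softmax across channels) so the grid is faithful;
ReLU / l2 / 0.01 is the documented default. Two implementation choices are
worth stating:

* **Regularizer normalization.** The penalty is per weight
  (`factor * mean(|w|)` or `factor * mean(w^2)` per layer), not the raw
  sum. Under Adam, an unnormalized sum over a first fully-connected layer
  with half a million weights dominates the loss and drives the layer to
  zero before the task gradient can shape it; the per-weight form keeps
  one factor comparable across layers of very different sizes.
* **Desk-scale defaults.** Filters default to (16, 32, 32, 48, 64) with
  5 px kernels — every layer inside the 16–128 range in which training
  converges, sized so a full train/evaluate cycle runs in minutes on one
  CPU. Optimizer settings are not dictated by the architecture; the
  defaults are Adam at learning rate 1e-3 (2e-3 in the bundled
  benchmarks), batch size 32, and an epoch budget chosen per experiment.

The engine (im2col convolution + BLAS gemm, exact backward pass, verified
against finite differences) takes all randomness — initialization and
batch order — from the configuration seed and is single-threaded, so
seeded training is bit-for-bit reproducible.

## The synthetic field simulator

Patient images behind the published results are not released, so every
pipeline stage is exercised on simulated fields with exact ground truth.
The simulator renders, per cell: an elliptical nucleus in DAPI with a flat
core and Gaussian shoulder (a pure Gaussian profile would put the Otsu
boundary well inside the true ellipse and depress IoU against ground
truth; the flattened profile keeps the rendered boundary sharp while
remaining smooth), CD45 staining at `cd45_positive_intensity` for
leukocytes over a slightly dilated footprint, and Gaussian spots in CEP8
and CEP17 placed on a jittered ring inside the nucleus. Ring placement
guarantees pairwise spot separation above the merge distance of detected
spots (the ring radius is floored so the chord between neighbours clears
about 2.3 spot radii plus margin), so ground-truth counts are unambiguous;
a `confluent_spots` toggle deliberately violates this to exercise the
merge rule. Additive Gaussian noise is clipped to the bit range. Ground
truth labels are *computed by the caller's own rule* from the true
features (CD45 status, spot counts), so generator and rule agree by
construction — the label-consistency test then verifies the whole imaging
and measurement chain, not the bookkeeping.

Cell placement rejects overlaps except for a designated `overlap_fraction`
of cells, placed so centers sit 1.8 mean radii apart (overlap of ~20% of a
radius — deep enough that plain segmentation merges the pair, shallow
enough that a distance-map saddle survives for the watershed). Class
composition defaults to 30% CTCs and 40% leukocytes per field, mirroring
the positive fraction of the published test split (300 of 1000); CTC cells
draw per-probe counts from 3–6, diploid cells from 1–2.

Benchmark tiers: `easy` (noise-free, separated), `noisy` (noise sigma 12
on an 8-bit range), `overlapping` (a second nucleus fused to the focal
cell in 20% of crops). What the simulator does **not** emulate: optical
PSF and chromatic shifts, photobleaching, autofluorescent debris,
chromatin texture, staining gradients, or the true morphological
variability of patient CTCs. Perfect scores on `easy` tiers therefore
validate the algorithmic chain, not clinical performance; the published
patient-level confusion matrices are reproduced only as worked examples of
the metric definitions.

## Evaluation

Confusion matrices count CTC_POSITIVE as the positive class. Sensitivity
(recall) is TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP), and
F1 the harmonic mean of precision and recall. A zero denominator makes a
metric *undefined* (`NA`), never 0 — a degenerate test set must not score
silently perfect or zero. AUC uses the rank (Mann–Whitney) statistic with
ties counting one half, checked against an all-pairs oracle.

Reported percentages round half away from zero to one decimal. The
reported F1 percentage is recomputed from the rounded precision and recall
percentages — the convention that matches how such tables are printed in
practice; the exact fractions remain in the metrics object and satisfy the
harmonic-mean identity to machine precision.

## Problem sizes in the bundled checks

The test suite and `scripts/acceptance.R` run at desk scale, chosen so a
full pass completes in minutes on a single CPU: rule-consistency on 20
noise-free 512x512 fields of 26 cells (520 cells); segmentation recovery
on 200 nuclei across 10 fields; watershed splitting on 12 fields with 40%
of cells in overlapped pairs; oracle checks on 1000 random spot-merge
instances, 100 histograms and 100 score vectors; the hyper-parameter grid
on 200 crops at 32 px input with 3 epochs per fold; final CNN training on
520 crops at 64 px for 8 epochs, evaluated on a held-out 300/700 split
(the published test-set class balance). The fidelity-scale field size
(2728 x 2192) and larger training budgets are plain parameter changes.

## Known limitations

* The rule-based caller's thresholds (area gates, solidity, CD45 weak-
  signal guard) are engineering defaults; real acquisitions will need
  per-protocol calibration.
* Watershed splitting degrades for overlaps much deeper than ~20% of a
  radius (no distance-map saddle exists); such events are excluded by QC
  rather than resolved.
* The CNN is trained and evaluated on synthetic crops only; no claim is
  made about transfer to patient images, whose variability the simulator
  does not model.
* Channels are assumed pre-aligned (as imFISH acquisition provides);
  there is no registration step. Hue decomposition of RGB composites is a
  convenience path and cannot losslessly separate red from orange.
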