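---
title: "Methods: label-free single-cell segmentation, mitosis detection and tracking in stem-cell colonies"
author: "colonytrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-free segmentation, mitosis detection and tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Induced pluripotent stem cells (iPSCs) grow in tightly packed colonies.
Quantifying single-cell dynamics — migration, division rates, lineage —
over a day or more of culture requires segmenting and tracking every
nucleus in phase-contrast time-lapse images, because continuous
fluorescence excitation is phototoxic. The strategy implemented here uses
a nuclear fluorescent label only *once*, to manufacture training
annotations automatically: classical image processing on the fluorescence
channel produces nuclear instance masks and mitosis labels at essentially
unlimited scale, and pixel classifiers trained on those annotations then
operate on phase contrast alone. An assignment-based tracker turns the
per-frame detections and division events into tracks and lineages, and a
metrics layer summarizes accuracy and biology (F1 scores, linkage error
rates, mean squared displacement, mitosis rates, doubling and
interdivision times).

All stages are exercisable end-to-end on synthetic time-lapse data with
complete ground truth, generated by the package itself.

## Automated annotation from fluorescence (refgen)

Nuclear reference objects come from a band-pass filter
(difference of Gaussians, nucleus preset sigmas 2 and 12 px) followed by a
threshold (Otsu by default, or a fixed empirical value), FogBank-style
separation of touching objects, and a per-object binary erosion with a
disk of radius 1. The filter constants are package choices; the underlying
workflow specifies the operations but not the scales.

Mitotic (class-2) candidates come from a second band-pass at the
condensed-DNA scale (sigmas 1 and 4 px). Condensed chromatin packs the
nuclear DNA into roughly one fifth of the interphase area, so with a
conserved fluorophore its intensity is about three times the interphase
body; the condensed preset therefore defaults to a fixed threshold of 0.8
on the filter response, above the response produced by two overlapping
interphase nuclei (whose summed brightness is only twice the body level).
An instance is flagged iff the above-threshold response area inside it is
between 10% and 90% of the instance area: genuine condensation is a
compact minority of the nucleus, while objects responding almost
everywhere are overlapping-nucleus artifacts.

Daughter identification follows the duplicate-and-assign scheme: every
flagged object at frame $t_0$ enters the linear sum assignment against
frame $t_1$ twice; a division is recorded iff its two copies map to two
distinct objects. Three refinements stabilize this in crowded colonies:

* the pairing cost is the same combined cost used everywhere else in the
  pipeline, $d/d_{\max} + (1 - \mathrm{IoU})$, rather than centroid
  distance alone — the daughters overlap the mother's footprint, which
  prevents neighbors whose own continuation vanished from "stealing" a
  daughter;
* a symmetry gate: the midpoint of the two mapped objects must fall
  within 4 px of the mother's centroid (daughters straddle the mother; a
  persisting mother whose duplicate captured a neighbor does not);
* condensation flags are propagated forward along nearest-centroid
  identity chains for up to 2 frames, and a flagged mother whose
  duplicates find no valid split at $t_1$ may match against $t_1 + 1$
  (daughters are sometimes entangled with a neighbor for one frame); the
  event is still dated $t_1$.

Re-detections of one division are removed by clustering events within
6 px and 8 frames; the member whose mother has the longest run of
consecutive condensation flags wins (condensation builds up over the
~10 minutes before division; spurious early splits have short runs and
post-division splits none), with ties resolved toward the smaller
combined daughter area and then the earlier frame.

The 4-class masks (0 background, 1 nucleus, 2 mitotic, 3 daughter) paint
the mother's pixels class 2 for the 5 frames before each division and the
daughters class 3 for 3 frames from the division on; overlapping windows
resolve in favor of the later event.

## FogBank-style object separation

`separateObjects()` follows the level-descent idea of the FogBank
algorithm. The quantized seed surface is walked from its top level down;
any connected component of $\{ \mathrm{surface} \ge L \}$ containing no
existing seed spawns a new one, provided its peak distance-transform depth
exceeds the erosion size (objects thinner than the erosion element never
seed themselves and fall to an orphan rule that seeds them whole). Growth
is a synchronized multi-source breadth-first expansion inside the mask —
geodesic nearest-seed assignment, simultaneous arrivals resolving to the
lower seed id. Objects below the minimum size merge into their largest
touching neighbor or are dropped when isolated, smallest first.

By default the seed surface is the Euclidean distance transform (1-px
levels). The fluorescence path instead seeds on the smoothed intensity
(scale-normalized, 32 levels) plus a small distance-transform term
(0.04 per px): real inter-nucleus gaps then separate seeds even when
band-pass smoothing has bridged the mask, while equal-brightness touching
nuclei still separate on the geometric term. Defaults `erodeSize = 2`,
`minSize = 9` sit mid-way in the band that maximizes detection F1 in the
package's own parameter sweep (erosion 1-4, minimum size 8-10).
2-D components are 4-connected throughout; spatiotemporal components are
26-connected.

## Pixel classifiers and ensemble voting (segmenter)

The trainable classifier is a multiscale convolutional feature bank —
Gaussian pyramid (sigmas 1, 2, 4, 8), difference-of-Gaussians and
gradient-magnitude channels, plus temporal mean/derivative channels in the
spatiotemporal mode — feeding a single-hidden-layer softmax network fit by
weighted cross-entropy. This ilastik-style design was chosen for exact
seed-determinism and CPU-friendly training/inference at package scale
while honoring the same training contract as a deep encoder–decoder
would: per-class loss weights (background:nucleus = 1:2 in the binary
mode; 1:2:20:20 for background:nucleus:mitotic:daughter in the 4-class
mode), reflection/rotation/Gaussian-blur augmentation, and stratified
pixel sampling so the rare mitotic classes are represented. `epochs = 0`
yields an untrained (randomly initialized) predictor so the downstream
pipeline can be exercised without optimization.

Inference uses 3 instances of the classifier differing only in their
training seed; per pixel, a decision is kept where at least 2 of 3
instances agree (binary: nucleus probability above 0.5; 4-class: argmax,
three-way ties resolving to the lowest class id). Because the features
are convolutional and the network pointwise, full-frame prediction equals
tile-wise prediction up to borders, so inference runs on whole frames.
The voted mask receives hole filling and a radius-1 opening — pixel-level
vote noise would otherwise corrupt the distance transform that drives the
object separation.

## Mitosis events from 4-class masks (mitosis)

Class-2 and class-3 voxels are merged and connected-component labeled in
(x, y, time) with 26-connectivity. Components must exceed 300 voxels and
span at least 10 frames (defaults matching the post-processing
rules the pipeline is built around; masks built from the default 5 + 3 annotation windows
span exactly 8 frames, so pass
`eventFilter(minPersistence = framesBefore + framesAfter)` for those).
The division time is the first frame at which the component's class-3
region splits into two 4-connected 2-D objects, falling back to the frame
of maximal class-2 area (earliest on ties). Daughter seeds are the two
class-3 centroids when the split is observed, otherwise the two points at
plus/minus half the mother's major-axis length along its orientation.

## Tracking and lineage (tracker)

Frame-to-frame linking is a gated linear sum assignment with cost
$w_d \, d / d_{\max} + w_o (1 - \mathrm{IoU})$, both weights 1 and the
gate at 15 px, so both terms lie in [0, 1]. Unmatched previous objects
coast for up to 5 frames (grace window) before their track closes;
unmatched previous objects whose pixels fell mostly (>50%) inside a
matched current object are recorded as merge events and closed rather
than coasted. Unmatched current objects open new tracks, ids assigned in
birth order. Division events bypass the assignment: the mother track
closes at the division, the two daughter tracks are claimed by the
instances nearest the event's seed positions (within the gate) and carry
the mother's id as parent. Coasting frames are not counted in per-frame
track totals. Track filtering removes tracks observed in fewer than 5
frames (10 minutes at 2-minute intervals), which brings per-frame counts
to within a few percent of the true cell count in the package's noisy
pipeline tests.

## Evaluation and dynamics metrics (metrics)

Detection accuracy matches reference and test objects by gated assignment
(cost as above, 15-px cutoff) and reports
$F_1 = 2\,TP / (2\,TP + FN + FP)$ plus the fractions of additional
(FP / reference count) and missing (FN / reference count) objects.
Mitosis events match on spatial distance with 15-px and 6-frame gates. A
linkage error is a frame at which the test id paired to a persisting
reference track changes; the rate divides by track length. Doubling time
from counts is $\ln 2 / (\ln(N_t/N_0)/t)$ on sliding windows (30 frames
by default); from mitoses, $\ln 2 / (\ln((N_0+m)/N_0)/t)$ — the two
diverge exactly when cells die, which the acceptance checks exploit.
Mitosis rates are sliding-window event counts normalized by the initial
(or per-window) cell count and smoothed by a 20-frame moving average.
MSD averages squared displacements over all lags up to a 60-minute
horizon (the horizon average was chosen over a single 1-h lag; the
convention is stated here because both are common). The colony mask for
edge-distance profiles is the morphological closing of the nucleus-mask
union with a disk of three median nucleus radii; per-cell distances are
distance-transform values at centroids, averaged in 25-um bins.

## The synthetic-data generator (simdata)

`simulateTimeLapse()` emulates the statistical structure the pipeline
assumes: elliptical nuclei (semi-axes 4-7 px at ~0.64 um/px) packed in
colony clusters, imaged every 2 minutes; Brownian per-frame displacements
with SD 1.0 px at the colony edge decaying to 0.4 px in the interior
(20-px length scale) — chosen to keep displacements well inside the 15-px
link gate while making the edge-vs-interior motility contrast clearly
resolvable; truncated-normal interdivision times (mean 15 h, SD 3 h,
lower bound 9 h, matching the observed ~15-h median and the 9-24-h
plausibility band); a condensed-DNA core at 3x the body intensity for the
5 frames before division (fluorophore-mass conservation under ~5x area
compaction); two small, just-separated daughters afterwards; additive
Gaussian noise. Nuclei relax apart to 1.05x the sum of their mean
semi-axes each frame — nuclear labels always show a non-fluorescent
cytoplasmic gap between neighbors, and without it the image degenerates
into a uniform carpet no band-pass can segment — but transient overlaps
between motion and relaxation steps remain, reproducing the
merged-object failure mode of real colonies. Rendering sums intensities
where nuclei do overlap. The phase-like channel is a deterministic
edge-enhanced, contrast-inverted transform of the same scene plus noise:
sufficient for training pixel classifiers, but it does not attempt
phase-contrast optics (halos, shade-off), so passing tests demonstrate
pipeline correctness, not performance on real microscopes.

Ground truth includes per-frame instance masks (labels are track ids),
4-class masks, track tables, lineage and division events with daughter
seeds. A fixed seed makes every output bit-reproducible.
`simulatePopulation()` is the non-imaging companion for population-scale
statistics: constant-hazard mode gives exact exponential growth at a
configured doubling time (used to validate the growth estimators at
n = 2000 cells), age mode reproduces the truncated-normal interdivision
model. Completed lifetimes in a growing culture are right-censor-biased
(most births are recent), so lifetimes carry their birth frames and
estimator checks restrict to the cohort born at least 24 h before the end
of observation.

`oracleClassifier()` wraps the ground truth as a predictor whose argmax
equals the true classes except at a reproducibly chosen flip fraction of
pixels — the device that lets ensemble voting, post-processing and
tracking be tested at any error level without training.

## Numerical choices and degenerate inputs

Assignments use the Hungarian method via `clue::solve_LSAP` with a
large-constant padding scheme: forbidden pairs (beyond the gates) and
rectangular problems are padded so that cardinality is maximized first
and cost minimized second; tests verify equality with exhaustive
enumeration on hundreds of random instances. Constant images are an
error for z-score normalization; empty masks, empty frames and empty
event lists are valid inputs everywhere downstream. Tile/untile uses
reflect padding and is bit-exact on the original extent. A degenerate
one-pixel mother yields coincident daughter seeds with a warning.

## Problem sizes

The bundled checks run at deliberately moderate scale: the clean
end-to-end culture uses 50 starting cells over 360 frames (12 h) on
256 x 256 px; the noisy-ensemble check 40 cells over 60 frames; training
uses 16 annotated frames of a 24-frame culture with three seeds;
estimator checks use 2000-cell populations (hazard mode) and 1200-cell,
48-h populations (age mode); the parameter sweep uses three 200 x 200
frames of touching paper-scale nuclei with specks and debris-scale
objects. These sizes were chosen so the complete validation remains
convenient on a laptop while every stage still operates in its intended
regime.

## Known limitations

* The phase-like rendering is a stand-in; no claim is made about
  real-microscope accuracy: reported real-data scores (average F1 ~0.94
  for nuclear detection, ~0.70 for mitosis detection) require external
  image data.
* Deeply or persistently overlapping nuclei merge — the documented
  failure mode; merge events are flagged but identities are not resolved
  retrospectively.
* About 15% of simulated daughter pairs are pixel-adjacent at birth, so
  mask-only division timing (the class-3 split rule) dates them 1-2
  frames late; the annotation chain's look-ahead pairing is the accurate
  path.
* The tracker is greedy frame-to-frame; no global trajectory
  optimization or appearance re-identification is attempted.
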