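---
title: "Monitoring broiler floor distribution from top-view imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring broiler floor distribution from top-view imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

How a broiler flock spreads over the pen floor — how many birds are at the
water line, how many at the feeder, how many resting or moving elsewhere —
is a day-to-day welfare and health indicator: lame or heat-stressed birds
cluster near resources, a healthy flock distributes evenly. Inspecting this
by eye in a commercial grow-out house is slow and subjective. `flockdist`
implements a machine-vision pipeline that turns a ceiling-camera frame into
three numbers: the bird counts in the drinking, feeding and rest/exercise
zones.

The pipeline has four stages:

1. **Segmentation.** After blanking everything outside the pen's detection
   rectangle, the frame is thresholded by two-dimensional Otsu analysis on
   a colour channel pair — by default the joint (green, blue) histogram,
   which separates light-feathered birds from brown litter better than the
   other RGB pairs. Morphological corrosion (disc erosion) and a minimum
   component area then clean the mask, and 8-connected regions are
   extracted.
2. **Counting.** Each region's pixel area $s_i$ is normalised by the day's
   single-bird reference area $s$ (the mean of single-bird profiles sampled
   that day): $\bar s_i = s_i / s$. A backpropagation-trained feedforward
   network with one input ($\bar s_i$), one sigmoidal hidden layer
   (10 units) and a linear output maps the normalised area to a bird
   count; without a trained model the direct rule
   $\mathrm{round}(\bar s_i)$ is used. Counts are rounded half away from
   zero and clamped to $\ge 1$ for any region that survived the area
   filter.
3. **Zonal assignment.** The floor is divided into a drinking rectangle
   (centred on the nipple-drinker line, one three-week-old body length
   wide), a feeding disc (feeder radius plus one body length) and the rest
   zone (everything else). A region belongs to a special zone when
   *strictly more than half* of its pixels fall inside it; exactly half
   goes to rest. A multi-bird region contributes its whole count to its
   single majority zone.
4. **Evaluation.** Over an evaluation set, per-zone tallies of true birds
   $T_{truenum}$, detected birds $T_{num}$, missed detections $T_{miss}$
   (by cause: crowding, occlusion, others) and false detections $T_{false}$
   give the rates
   $R_{accuracy} = T_{num}/T_{truenum}$,
   $R_{miss} = T_{miss}/T_{truenum}$,
   $R_{false} = T_{false}/T_{truenum}$,
   reported half-away-from-zero to 4 decimals. Count-model quality is
   summarised by $R = 1 - \sum(y_i-\hat y_i)^2 / \sum(y_i-\bar y)^2$,
   $\mathrm{MSE} = \sum(y_i-\hat y_i)^2/n$ and
   $\mathrm{MAE} = \frac1n \sum |y_i-\hat y_i|/y_i$. Note this MAE divides
   each error by the actual count — it is a *relative* error despite its
   name, and is implemented exactly as defined; `pearson_r()` provides the
   conventional correlation separately.

## Two-dimensional Otsu, precisely

`build_joint_histogram()` quantises two per-pixel features to $L$ levels
(default 256) and counts them on an $L \times L$ grid. Two feature modes
exist because "two-dimensional" thresholding appears in two forms in the
imaging literature:

* `joint` (default): the two features are two colour channels (G and B).
* `value_vs_neighborhood`: a channel's value against its 3×3 neighbourhood
  mean — the classical formulation, robust to isolated noise pixels.

`otsu_2d()` scans all $L^2$ threshold pairs with integral images and
returns the pair maximising the trace of the between-class scatter of the
two quadrant classes (at-or-below both thresholds vs strictly above both)
about the global mean; the off-diagonal quadrants contribute to the global
mean but to neither class, as in the classical method. Ties — including
the float near-ties that arise when different threshold pairs induce the
same partition of a sparse histogram — resolve to the smallest $(t_1,
t_2)$. A histogram with all its mass in one bin returns that bin with
objective 0 and a degenerate flag. The implementation is verified against
an exhaustive-search oracle on hundreds of random histograms with
$L \le 16$.

Binarisation needs a polarity: which quadrant is "bird"? The paper of
record never says whether birds are the bright class, so
`apply_threshold()` picks the quadrant whose mean colour lies farther from
the median pen colour (preferring the smaller class on a tie): birds are
the minority class and differ most from the litter-dominated median,
whether the flock is light on dark litter or the reverse. A minimum
foreground/background contrast (default 30 8-bit RGB units) guards the
degenerate case of a birdless pen, where an unguarded threshold would
split the litter noise in half.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `levels` | 256 | gray levels | full 8-bit resolution; tests use ≤ 16 for brute-force checks |
| `erosion_radius` | 1 | px | cuts thin bridges from equipment edges in field imagery; radius 1 is the 4-neighbour cross. Synthetic evaluation runs use 0 — the generator's noise produces no speckle, and erosion shifts boundary-straddling zone fractions |
| `min_area` | 30 px at 1440×1080, scaled by image area | px | discards sub-bird speckle |
| `min_contrast` | 30 | 8-bit RGB distance | empty-pen guard (above) |
| `hidden_sizes` | 10 | units | one sigmoidal hidden layer, the conventional width for a 1-D regression of this kind |
| `epochs` / `patience` | 500 / 20 | iterations | Levenberg–Marquardt with validation-based early stopping |
| body length | two × semi-major axis of a 21-day bird | px | fixes the zone geometry at the three-week-old calibration, static across days |

The counting network is trained by Levenberg–Marquardt on the squared
error from a Nguyen–Widrow-style initialisation (steep sigmoids with
transition centres spread over the input range) — the classical
configuration for a small single-hidden-layer regression network. The data
are split 0.70/0.15/0.15 (training/validation/test) by a seeded shuffle.
First-order optimisers were tried and rejected here: on step-like
area-to-count data they stall for hundreds of epochs in the smooth
near-identity minimum, while LM sharpens the sigmoid transitions within
tens of iterations and is deterministic given the seed. The architecture
has exactly one hidden layer; deeper configurations are out of scope.

Because birds grow markedly between 18 and 35 days of age, every day is
calibrated separately: the reference area $s$ is re-estimated from
single-bird profiles of that day (`calibrate_reference_area()` renders and
segments single-bird scenes with the *same* segmentation settings as the
detection run, so systematic area biases cancel in the ratio). The
normalised areas are therefore age-free and a single count model serves
all days.

## The synthetic pen generator

Real pen imagery from the source study is not available, so `flockdist`
ships a scene generator that renders what that camera saw and — unlike the
field data — knows the exact truth. It emulates:

* a fixed pen with 19 birds (21 reared, two removed for health sampling);
* light elliptical silhouettes (axis ratio 1.6) on darker litter, with
  per-day area growth linear from 600 px (d18) to 1500 px (d35) at the
  480×360 reference frame, scaling with image area;
* per-bird area jitter (lognormal-ish, sd 8% — within-flock size
  variation), additive pixel noise (sd 8 on the 8-bit scale);
* equipment occluders (feeder chain, water line) drawn over the birds,
  with per-bird occluded fractions recorded;
* crowding: a configurable fraction of birds placed as touching pairs or
  triples (tangency enforced against every cluster member, so a $k$-blob's
  union area is close to $k$ single-bird areas);
* wing spreading: a configurable probability of inflating a silhouette's
  area by 1.5×.

Occluders, crowding and wing spreading default *off*: they are failure-mode
knobs that studies enable explicitly. `generate_area_count_pairs()` builds
the counting network's training library — union areas of 1–4 touching
silhouettes with a 2% measurement noise, paired with the exact count —
standing in for the manually curated single-and-merged-blob library of the
original field study.

What the generator does **not** emulate: feather texture, shadows and
lighting gradients, dust on the lens, birds at the pen wall being clipped
by the camera frustum, motion blur. Passing tests on synthetic scenes
therefore demonstrate the *algorithmic* correctness of segmentation,
counting, zoning and evaluation — not field robustness, which in the
original study is degraded by exactly the occlusion and crowding mechanisms
the generator reproduces in idealised form.

## Numerical choices and degenerate inputs

* All reported rates and all area-to-count conversions round half away
  from zero (`round_half_up()`), so `.5` boundaries never depend on the
  platform's banker's rounding.
* Connected components are 8-connected, labelled by a run/union-find pass,
  and returned ordered by bounding-box (ymin, xmin) for reproducibility.
* Disc erosion uses the exact Euclidean offset set
  $\{(dy,dx): dy^2+dx^2 \le r^2\}$; border pixels erode against an
  implicit background frame.
* Determinism: every stochastic operation (scene placement, noise, data
  splits, clustering initialisation) runs under a caller-supplied seed via
  an RNG-state-preserving scope, so identical inputs give bit-identical
  outputs.
* K-means (via `stats::kmeans`, Lloyd) and fuzzy c-means baselines pick
  the bird cluster by the same farthest-from-median rule; FCM gives a
  pixel at zero distance from a centre full membership there, and its
  objective trace is non-increasing by construction. Their runtimes are
  reported by `timing_harness()` but never asserted — clustering speed is
  hardware-bound.
* `fit_metrics()` refuses series with zero count variance (R undefined) or
  a zero actual count (relative MAE undefined).

## Evaluation-study design

The packaged acceptance studies run at desk scale: 320×240 frames
(bird areas scale accordingly), 19 birds, the default noise level. The
distribution-recovery study uses 200 frames across days 18, 24, 30 and 35
(50 each, per-day reference recalibration), a crowding fraction of 0.1
(one touching pair per frame) and a trained count model.

One property of the majority-zone rule is worth knowing when reading its
results: when a touching pair spans a zone boundary with split per-bird
labels, the merged region's whole count goes to its majority zone, so that
frame's per-zone counts are off by ±1 *by construction* — the ground truth
labels each bird individually, the rule cannot. With this pen geometry
(drinking band plus feeding disc cover roughly a quarter of the floor) a
mixed-zone pair occurs in roughly one frame in seven at one pair per
frame, which bounds per-frame exactness near 0.86 even though the per-zone
accuracy rates stay near 1.0 (the ±1 transfers largely cancel in the
accumulated tallies, surfacing as matched miss/false pairs). Splitting a
region's count across zones would remove the effect but is a different —
and for single-zone regions worse — reading of the summation rule.

A second documented quirk: in the published evaluation table the feeding
row prints an accuracy of 0.9544 and a false-detection rate of 0.0037,
but the printed counts give 785/823 = 0.9538 and 3/823 = 0.0036. The
package reports what the definitions compute; the one-digit discrepancies
are presumed rounding/transcription artefacts of the source table and are
not reproduced.

## Limitations

* The zone geometry is static (three-week-old body length) while birds
  grow; late-cycle birds straddling a boundary are assigned slightly
  differently than a per-day geometry would.
* Counting is area-based: a wing-spreading bird inflates its blob by ~1.5×
  and rounds to 2 — the over-count mechanism the failure-mode knob
  reproduces. Posture recognition is out of scope.
* Severely occluded birds (over half hidden) vanish from the mask and are
  missed; the evaluation attributes such misses to occlusion from the
  ground truth. Multi-camera fusion is out of scope.
* Video ingestion is out of scope; frames are read from image files.
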