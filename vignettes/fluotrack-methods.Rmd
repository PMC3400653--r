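---
title: "Methods: fluorescence video tracking with fluotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fluorescence video tracking with fluotrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluotrack)
```

fluotrack analyses dark-field video of fluorescent animals — typically
adult *Drosophila* expressing a GFP reporter, filmed through emission
filters so that only light emitted by the animals reaches the sensor —
recorded by two synchronized, calibrated cameras aimed at a cylindrical
observation chamber. This vignette is the package's account of the
models and numerical choices behind each stage.

## Background model and silhouette detection

Each camera view is static, so the background is modelled independently
at every pixel by a running Gaussian: a per-pixel mean $\mu$ updated by
the selective exponential rule

$$\mu \leftarrow (1 - \alpha)\,\mu + \alpha I$$

applied **only at pixels classified as background** in the current
frame. A pixel is foreground when $|I - \mu| > T$ on the detection
channel. The two parameters:

* $\alpha$ (adaptation rate, dimensionless, default 0.05). 0 freezes
  the model, 1 replaces it every frame. The default favours stability:
  multi-hour dark-chamber recordings drift slowly, and a small $\alpha$
  keeps a briefly resting animal from being absorbed. The flip side is
  real and documented below: an animal that rests for many multiples of
  $1/\alpha$ frames, or whose brightness changes slowly *in place*,
  merges into the background. Motion is what makes this detector work.
* $T$ (threshold, intensity levels, default 40). $T$ is empirical: it
  depends on lamp brightness, filter set and exposure, is tuned once per
  rig (the `preview_threshold()` masks exist for exactly this), and is
  then held fixed across every video of an experiment so numbers stay
  comparable. Classification deliberately uses a fixed $T$ rather than a
  variance-scaled test; a per-pixel variance can be tracked, but only as
  a diagnostic.

The initial model is the per-pixel mean of a small evenly spaced sample
of the whole recording (`sample_fraction`, default 1%, never fewer than
2 frames, first and last always included). With widely spaced samples a
moving animal occupies any given pixel in only a few of them, so its
contribution is diluted to a few levels. This premise fails for very
short clips: 1% of 60 frames is 2 samples, and an animal present in
both leaves a bright "ghost" in the initial mean which, being classified
foreground forever, is never repaired by the selective update. Short
synthetic fixtures therefore raise `sample_fraction` (the tests use
0.2–0.25); real hour-scale recordings are what the 1% default is for.

Intensities are 8-bit integers, 0–255, per RGB channel. Detection runs
on one channel (green for GFP; configurable for red/blue reporters).

## Mask cleaning and components

The binary change mask is opened (eroded then dilated) with a 3×3
square structural element, which deletes speckle smaller than the
element and leaves animal-sized regions essentially unchanged.
Out-of-image neighbours count as background, so a silhouette touching
the frame edge loses its one-pixel rim — ordinary erosion semantics.
Foreground pixels are then partitioned into maximal 8-connected
components (configurable to 4; 8 is the default so thin diagonal
fragments of one animal stay joined), ordered deterministically by
bounding-box corner. Components smaller than `min_component_size` are
removed; the boundary is strict — a component of exactly the threshold
size survives. Centroids are unweighted means of member pixel
coordinates: the silhouette is binary, so its center of mass is
geometric, not intensity-weighted.

Both the opening and the labelling are implemented directly in the
package (vectorised shifts and minimum-label propagation). The border
convention and the 4/8-connectivity switch are part of the contract
above, and the test suite checks both against brute-force set-definition
and flood-fill oracles on random masks.

## Fluorescence quantification: four intensity bins

For every retained component and every channel, member pixels are
binned by intensity into four bins of increasing brightness, and both
pixel counts and per-bin intensity sums are recorded. The default edges
are the equal-width quartiles of the 8-bit range — [0,64), [64,128),
[128,192), [192,256) — the parameter-free choice; they are
configurable. A plain mean over the silhouette would dilute a reporter
confined to a small bright region (eyes, CNS) by the large dim rest of
the body; the bins keep that signal separate, and in practice
autofluorescence and residual background land almost entirely in bin 1.

To compare samples, the highest bin populated in *every* sample is
used; if the top bin is empty for some sample the next lower bin is
added, and so on (`select_reporting_bin()`), giving a contiguous,
top-anchored bin set. Time courses pool the selected-bin intensity sums
over all components in both views by **summation** (the choice matters
for multi-animal vials and is fixed here: sums, not means, so a group
of animals reads as the group's total signal).

Per-frame values are averaged per minute (blocks of
$60 \times \text{frame rate}$ frames; a trailing partial minute
averages what it has). Frames with no detection contribute 0 by
default — an animal at rest long enough joins the background, so the
conservative reading is an under-count — or can be skipped. The
per-minute series is smoothed by LOESS, span 0.1 and degree 2 by
default, computed exactly (`stats::loess` with a direct surface, no
robustness iterations); each local fit needs `floor(span * n)` points
and at least `degree + 2` of them, so a series must have
`ceiling((degree + 2)/span)` points (40 at the defaults) before
smoothing is attempted.

`detect_onset()` is an explicitly added convenience, not part of the
classical readout (induction times are traditionally judged from the
smoothed plot): onset is the first minute exceeding the baseline mean
plus $k$ baseline standard deviations that holds for 10 consecutive
minutes.

## Camera model and 3D reconstruction

Each camera is a 3×4 projection matrix $P$, defined up to scale,
mapping homogeneous world points to homogeneous pixels
($s\,[u,v,1]^\top = P\,[X,1]^\top$). Matrices enter as plain-text files
(3 rows × 4 numbers, `#` comments allowed) produced by any external
calibration; `fit_projection_matrix()` offers a direct-linear-transform
fit from ≥ 6 known correspondences for building synthetic rigs. The
optical center is recovered as the right null vector of $P$; a
rank-deficient left 3×3 block or a null vector at infinity is rejected
with a distinct error. Pixel convention everywhere: `u` = column, `v` =
row, 0-based, origin top-left (the package's component centroids are
1-based matrix indices and are converted at the pairing step).

A detected centroid back-projects to the ray from the optical center
through its pre-image; two rays from paired views rarely intersect
exactly, so the 3D position is the midpoint of their shortest
connecting segment, found in closed form from the 2×2 normal equations
of the perpendicularity conditions. The segment length (the *gap*) is
reported with every point rather than discarded: it is the natural
per-frame diagnostic of calibration and measurement quality, and users
can filter on it. Rays within ~$10^{-9}$ of parallel are refused as
degenerate.

Only frames with exactly one retained component in each view are
triangulated. Frames missing a detection in either view are skipped and
tallied (animals are routinely invisible to one camera depending on
pose); frames with several components are also skipped, because
cross-view correspondence between identical-looking animals is
undefined without extra assumptions — groups still get full
fluorescence output, just not 3D.

## Motion statistics

Speeds are Euclidean displacements over elapsed time between
consecutive track points; gaps longer than `max_frame_gap` (default 30
frames) break the series rather than fabricating a straight-line speed
across the unseen interval. Heading changes count interior points where
the angle between incoming and outgoing displacement vectors exceeds a
threshold (default 90°); the statistic has no canonical definition in
the field, so the displacement-angle form is adopted and the threshold
exposed. Zero-length displacements carry no direction and are skipped.

## Synthetic scenes: what they emulate and what they do not

The generator renders one or more blobs moving along known 3D paths
(helix, reflected bounded random walk, or stationary) inside a
cylindrical chamber, viewed by two pinhole cameras at right angles. A
blob is an isotropic 2D Gaussian spot: the pipeline uses only area,
centroid and intensity, none of which is shape-specific, so a fly-shaped
sprite would add realism without adding test power. Frames are
`background_level` plus clipped (not wrapped) Gaussian noise plus the
blob profiles; all noise is seeded per (scene seed, view, frame), so
in-memory, streamed, chunked and on-disk renderings of the same
configuration are bit-identical. Ground truth (3D position, per-view
projections, in-view flags, rendered intensity sums) is exported
alongside. Blobs whose projected center leaves a view are rendered
absent there and flagged, emulating occlusion rather than erroring.

Default scene conditions: 320×240 frames at 30 fps, a chamber
proportioned like a culture vial (height three times the radius; world
units read naturally as mm: radius 12.5, height 37.5), blob peak
intensity (30, 200, 30) RGB — a bright GFP reporter with faint
bleed-through — on background level 10 with noise SD 2. Detectability
is enforced at construction (peak must exceed background by more than
three noise SDs).

What passing tests on these scenes **do not** show about real videos:
no lens distortion or calibration error (real gaps will be larger), no
photometric saturation structure, no animal-shaped silhouettes or
leg/wing fragmentation, no reflections from vial walls, and no
slow lighting drift. The geometry, bookkeeping and statistics are
exercised fully; absolute detection rates on real footage still depend
on tuning $T$ per rig.

## Numerical choices and degenerate inputs

* Opening/labelling: out-of-image = background; ties in component order
  broken by (min_row, min_col); label propagation iterates to a fixed
  point, so results are scan-order independent.
* Triangulation: degenerate geometry errors at $|\sin\theta| \le
  10^{-9}$; projection errors for points on the principal plane.
* LOESS: exact direct fit; tricube weights vanish at the window edge;
  series shorter than the minimum raise an error naming it.
* Background means live in [0, 255] by construction; classification
  compares real-valued $\mu$ with integer frames without rounding.
* Per-minute blocks may be fractional when `frame_rate` is below one
  frame per second (block membership is `floor((i-1)/(60 fps))`),
  supporting slow time-lapse scenes.
* All RNG use is locally seeded and restores the caller's RNG state.

## Problem sizes used by the shipped checks

The package's own verification runs at sizes chosen to represent the
study conditions while staying quick to execute: the end-to-end
two-view recovery uses the default 600-frame 320×240 helix scene
(recovering ≥ 95% of in-view frames with mean 3D error under 2% of the
chamber diameter; measured values are ~100% and ~0.2%); the induction
recovery uses a 600-frame time-lapse at 10 frames/minute with a
sigmoid brightening programmed at minute 30 (onset recovered within the
smoothing window; measured exactly at minute 30); oracle-equivalence
suites run on 100 random instances per operation; chunking invariance
compares a 90-frame fixture processed whole versus in three chunks,
byte-identical. `scripts/acceptance.R` recomputes all of these from
scratch.

## Known limitations

* Multi-animal 3D tracking is out of scope (no cross-view identity).
* A motionless animal, or one whose reporter brightens slowly in place,
  fades into the adaptive background; only moving animals are tracked.
* Fluorescence values are camera-level intensity sums, not calibrated
  fluorophore quantities; no spectral unmixing.
* No lens-distortion model; projection matrices are trusted as given.
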