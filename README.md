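# fluotrack

Quantifying movement and gene expression in free-moving fluorescent
animals — typically adult *Drosophila* carrying a GFP reporter — from
dark-field video recorded by two synchronized, calibrated cameras.
Because the chamber is filmed through emission filters, each animal
appears as a bright silhouette on a dark background; fluotrack turns a
pair of such recordings into per-animal fluorescence time courses and a
3D trajectory with motion statistics.

The pipeline, stage by stage:

1. **Background subtraction.** Each pixel's background is a running
   Gaussian mean, updated selectively with adaptation rate α:
   `μ ← (1−α)μ + αI` at background pixels only. A pixel is foreground
   when `|I − μ| > T` on the detection channel; `T` is empirical, tuned
   once per rig and held fixed across an experiment. The initial model
   averages 1% of frames sampled at even intervals.
2. **Silhouettes.** The binary change mask is opened with a 3×3 square
   element, 8-connected components are extracted, size-filtered, and
   reduced to geometric centroids.
3. **Fluorescence.** Component pixels are split per channel into four
   intensity bins (G1–G4 for green, of increasing brightness), keeping
   per-bin counts and intensity sums. Reporter signal lives in the high
   bins; background and autofluorescence stay in G1, so binning beats a
   plain mean when signal is confined to a small bright region. Across
   samples, the highest bin populated in all samples is the reporting
   bin (topping up with the next lower bin when needed). Per-minute
   means are LOESS-smoothed (span 0.1, degree 2).
4. **3D reconstruction.** Each camera is a 3×4 projection matrix `P`
   (`s[u,v,1]ᵀ = P[X,1]ᵀ`) with optical center from its null space.
   Paired one-per-view centroids are back-projected to rays and
   triangulated at the midpoint of the rays' shortest connecting
   segment; the segment length ("gap") is kept as a quality diagnostic.
5. **Motion statistics.** Speeds from consecutive displacements (long
   detection gaps break the series) and heading-change frequency from
   displacement-angle threshold crossings.

A synthetic scene generator (Gaussian-profile blobs on known 3D paths
inside a cylindrical chamber, rendered through two pinhole cameras,
with exported ground truth) makes the whole pipeline testable without
recorded video.

## Worked example

Render a seeded two-view scene of one blob climbing a helix inside the
chamber, run the full pipeline, and compare against ground truth:

```r
library(fluotrack)

cfg  <- scene_config(n_frames = 150, random_seed = 19)   # 320x240 @ 30 fps
cams <- default_cameras(cfg)
tr   <- make_trajectory("helix", cfg)

av <- lapply(1:2, function(v)
  analyze_view(scene_frame_source(list(tr), cams, cfg, v),
               config = list(sample_fraction = 0.1), view_id = v))
pr  <- pair_observations(av[[1]]$detections, av[[2]]$detections)
trk <- reconstruct_trajectory(pr, cams[[1]], cams[[2]], cfg$frame_rate)
trk
#> <trajectory3d: 150 points, frames 1-150, median gap 0.0308>
motion_summary(trk)
#> <motion_summary: 150 points; mean speed 33.63, path 167; 0 heading changes (0 /s)>
head(as.data.frame(trk), 3)
#>   frame        x          y        z        gap
#> 1     1 8.746146 0.01425764 5.631370 0.01187656
#> 2     2 8.638924 1.15909045 5.820642 0.02084070
#> 3     3 8.460747 2.26078078 6.008423 0.04215889
```

All 150 frames are recovered; the median ray gap of 0.03 world units
(0.1% of the 25-unit chamber diameter) says the two viewing rays nearly
intersect, i.e. detection and calibration agree. The mean speed of
33.63 units/s matches the helix's analytic speed (33.6) to 0.1%.
`plot(trk)` draws the vial-shaped top and side views of the trajectory.

For file-based batch work, `write_scene_fixture()` writes per-view PNG
directories, projection-matrix text files and a ground-truth CSV, and
`run_batch(run_config(...))` processes such a recording in chunks with
a persistent background model, emitting detections, fluorescence,
per-minute, trajectory and summary CSVs. The same operations are
available from the shell via `inst/cli/fluotrack`
(`synth`, `preview-threshold`, `batch`, `track`, `fluor`, `plot-track`).

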