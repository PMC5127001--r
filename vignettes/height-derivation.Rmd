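---
title: "Direct crop-height derivation from nadir depth-camera point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct crop-height derivation from nadir depth-camera point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Crop height maps feed biomass and yield estimation and site-specific field
management. The usual workflow needs two surveys: a bare-terrain model
(DTM) before the crop emerges and a surface model (DSM) when it has grown.
`nadirchm` implements the alternative this package is built around: deriving
a crop height model (CHM) and individual plant heights from a **single**
campaign, using a low-cost time-of-flight (TOF) depth camera looking
straight down (nadir) into the stand. From above, gaps in the canopy expose
the ground, so per-cell *minimum* elevations sample the terrain while
per-cell *maxima* sample the canopy:

    CHM = DSM - DTM,   DSM(cell) = max z,   DTM(cell) = min z.

No interpolation is used; the method stands or falls with the coverage of
ground and canopy, which is why combining frames from several positions is
central.

Because no field data ship with the package, everything is exercised on a
synthetic maize plot rendered by a built-in virtual sensor with known ground
truth. The synthetic scene is first-class, tested code, and it defines the
study conditions for all end-to-end tests.

## Sensor model

The depth camera is modelled as a pinhole frustum (`frustum_spec()`):
70° x 60° field of view, 512 x 424 pixels (217,088 range measurements per
frame), usable boresight depth 0.5-4.5 m. The near/far limits are treated
as boresight *depth*, giving a flat-capped pyramid; this is the convention
that makes the triangulated boundary mesh used for artefact distances
(`frustum_face_distances()`) consistent with containment and clipping. The
theoretical measurement spacing, `2 r tan(angle/2) / n_pixels`, runs from
1.4 mm at 0.5 m to 10.9 mm at 4.0 m range for this geometry.

Two error components are modelled along the measurement ray
(`noise_model()`):

* precision — Gaussian range noise, interpolated linearly between 1 mm at
  0.8 m and 3 mm at 4.0 m;
* accuracy — a systematic range bias, by default negative (ranges
  underestimated) with magnitude from 5 mm at 0.8 m to 24 mm at 4.0 m.

These anchors reproduce the plane-target characterization figures that
`plane_precision_accuracy()` measures back from virtual scans
(`render_plane_scan()`), using a RANSAC plane fit restricted to the inner
third of the field of view (lens distortion at the frame edges is not
modelled; cropping to the FOV center is how the physical experiment avoided
it too).

Measurement artefacts — spurious points in empty space — are injected by
`artefact_model()`. Per-frame counts are Normal (truncated, rounded) with
lighting-dependent means (night 50, diffuse 195, sun-facing-away 202,
into-sun 218); 85% of artefacts are placed within 2 cm of the frustum
boundary faces and the rest uniformly in the volume, which reproduces the
small median but large maximum/SD of artefact-to-boundary distances seen in
empty-scene scans. The "into-sun" artefact column has no quantitative
description to build on; its geometry is an arbitrary parameter and is kept
out of all quantitative checks.

## The virtual scene

`generate_field()` lays out 52 plants on a jittered grid in a 2.5 m x 8.0 m
plot (mean longitudinal spacing 0.58 m, transverse 0.46 m) with heights
increasing south to north from 0.55 m to 2.41 m, emulating a shading
gradient. Each plant is a stylized geometric stand-in for maize: a vertical
stem tapering to a fine apex (the apex sits *exactly* at the true height,
which is the tested invariant) plus arched leaf blades. It is not a
botanical model; it exists to create occlusion, canopy gaps, and fine
apices — the three surface features the method is sensitive to.

`render_depth_frame()` renders one ray per pixel. Terrain (an analytic
plane) is intersected exactly; plant surfaces are densely pre-sampled into
area-weighted, normal-carrying "splats" (`sample_field_surface()`, default
4 mm spacing) and z-buffered per pixel. One resolution effect is modelled
deliberately: a TOF pixel integrates signal over its footprint, so
structures much finer than a pixel are measured low or not at all. Per
pixel, the nearest depth cluster (splats within 5 cm of the closest one) is
accepted only if its ray-projected area reaches `fill_fraction` (default
0.5) of the pixel footprint at that depth, and the returned depth is the
cluster's area-weighted mean. A fine stem apex therefore comes back a few
centimeters low — the mechanism behind the systematic crop-height
underestimation such sensors show, and the package tests that coarsening
the apex (`tip_radius` up) monotonically shrinks that bias. The virtual
laser scanner (`render_tls_scan()`) applies no fill criterion — a narrow
beam resolves the apices — which is exactly what makes it the reference
instrument.

`default_campaign()` renders 8 nadir frames advancing monotonically along
the plot's long axis and 5 elevated laser scans around the plot, all in one
world frame with known truth. Two geometry choices are the package's own:
the sensor's 70° axis spans the 2.5 m plot *width*, and each frame sits a
fixed 2.05 m above the locally highest plant. That clearance makes the
clipped footprint cover the plot width, gives overlapping frames along the
8 m axis, and averages ~3.75 m mounting height over the default field. The
campaign renders the reference scans at a 0.12° angular step (≈8 mm point
spacing at plot scale) rather than the instrument-level 0.029° default of
`render_tls_scan()`; at 0.25 m cells this still leaves hundreds of points
per cell and keeps a full render-process-assess cycle under a minute on one
core. These problem sizes are stated here as the package's chosen defaults.

## Processing chain

The order is fixed: `clip_to_top_fov()` → `crop_to_aoi()` → `sor_filter()`.

* **Top-FOV clipping** keeps only points whose lateral sensor-frame
  coordinates fall inside the FOV rectangle evaluated at the depth of the
  highest plant. This removes the FOV-edge artefact band and the splayed
  lower frustum margin in one cut. The rectangle is closed (boundary points
  kept): ties must never silently drop canopy-top points. On the synthetic
  campaign this step retains roughly a third of each frame's pixels,
  consistent with single-campaign field practice.
* **Statistical outlier removal**: for each point, the mean distance to its
  k = 5 nearest neighbors; points with `d_i > mean(d) + 1.0 sd(d)`
  (strictly) are removed. The literal reading "d_i larger than the SD of the
  distances" would strip nearly everything from finely sampled clouds; it is
  available as `rule = "sd_only"` for comparison, but the mean+SD form of
  the standard filter is the default. Neighbor searches are exact
  (grid-indexed, C++), not approximate, so results are reproducible
  bit-for-bit.
* **Registration** (`rigid_from_tiepoints()`) solves the no-scale rigid
  alignment in closed form (SVD/Kabsch) and reports the residual-distance
  SD, the quality figure used in the field workflow. The synthetic frames
  come with known poses, so the campaign itself does not need it; the
  solver is exercised against constructed transforms and an independent
  Procrustes fit.

Rasterization (`rasterize_extreme()`) uses half-open 0.25 m cells anchored
at the AOI corner, with points on the AOI's max edge folded into the last
cell, so every point maps to exactly one cell and all rasters (single
frames, combinations, reference) share one grid. `trim_border()` masks the
outermost ring — cells only partly covered — without shrinking the grid, so
all rasters stay co-registered. For the full plot this leaves 240 of the
10 x 32 cells.

## Plant heights

Two extraction scenarios:

1. **Unknown positions** (`heights_scenario1()`): canopy local maxima
   (strictly highest within a 0.125 m horizontal disc, first-index
   tie-break) minus the lowest point within the same radius; heights below
   0.500 m are discarded as non-plants. The 0.125 m local-maximum
   neighborhood radius is a package choice — only the minimum-extraction
   and matching radii are prescribed by the workflow this implements — and
   is exposed as a parameter.
2. **Known positions** (`heights_scenario2()`): max minus min within
   0.125 m of each given stem position; empty discs are reported as
   missing, never dropped silently.

`match_to_reference()` pairs observations with the nearest reference local
maximum within 0.125 m (unmatched ones are counted), and
`compare_heights()` reports the OLS fit (R²) plus the median, SD and RMSE
of the paired differences.

One subtlety the tests encode: a *favorable* single frame (few, fully
visible plants) can individually reach an R² as high as the combined
cloud's. The meaningful comparisons are (a) the pooled single-frame pairs
— every plant seen by every frame covering it, which is how single-cloud
scatter is naturally reported — against the combined cloud, and (b) the
exact per-plant domination: the combined cloud is a superset of each frame,
so its per-plant max can only rise and its min only fall, hence combined
heights are never below single-frame heights.

## Accuracy assessment

`accuracy_report()` computes, over valid difference-raster cells: RMSE,
mean, SD; mean/SD after removing blunders (|Δh| > 3·RMSE); the signed
median (q50) and the 68.3% and 95% quantiles of |Δh|; the NMAD

    NMAD = 1.4826 * median(|Δh_i - median(Δh)|),

a robust spread estimator consistent for σ under normality; and a Q-Q
normality score (squared Pearson correlation of the sorted standardized
differences against Normal quantiles — reported as `NA` for constant
differences, where it is undefined). Quantiles use linear interpolation
between order statistics (R type 7); none of the assessed conventions
prescribe a quantile method, so the R default is used and stated.
`cellwise_fit()` adds the per-cell OLS of test against reference CHM.

The robust/classical split is tested explicitly: NMAD and the median ignore
a few percent of gross blunders while RMSE and SD blow up; for Normal
differences NMAD/SD → 1, for heavy-tailed ones NMAD < SD.

## Numerical choices and degenerate inputs

* Closed boundaries everywhere a point could sit on an edge (AOI crop,
  top-FOV rectangle, frustum containment, disc queries).
* Strict inequality in the SOR threshold, so a perfectly regular grid
  (SD = 0) loses nothing.
* Local-maximum ties broken by lowest point index; deterministic.
* RANSAC: 0.01 m threshold, 500 iterations, explicit seed, total-least-
  squares refinement on the consensus set; collinear inputs are an error,
  not a silent bad fit.
* Empty clouds rasterize to all-nodata with a warning; all-nodata
  difference rasters and sub-2-pair comparisons are errors.
* All randomness (field layout, noise, artefacts) flows from explicit
  seeds; renders are bitwise reproducible.

## What the synthetic tests do and do not show

Passing the end-to-end tests shows the *pipeline* recovers known heights
under realistic sensor physics: occlusion, canopy gaps, range noise and
bias, sub-pixel apex loss, edge artefacts. It does not validate maize
morphology (the plants are stylized), wind-induced movement (not modelled;
the field protocol avoided it too), multipath/flying-pixel physics beyond
the pixel-fill approximation, lens distortion, or registration error
between sensors (synthetic poses are exact, so cross-sensor comparisons
here are free of the 0.5-3 cm co-registration uncertainty a real campaign
carries). Absolute error magnitudes on real fields will differ; the
qualitative structure — underestimation concentrated at fine canopy tops,
large gains from combining perspectives, robust statistics resisting
blunders — is what the synthetic campaign is designed to reproduce.
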