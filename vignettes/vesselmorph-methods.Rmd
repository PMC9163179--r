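---
title: "Edge-based vessel segmentation and morphometry: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-based vessel segmentation and morphometry: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmorph)
```

## The problem

Propagation-based phase-contrast microtomography (PC-µCT) of unstained,
paraffin-embedded brain tissue resolves the microvasculature without any
contrast agent — but the former vascular space has no consistent intensity.
Where collapsed vessel walls or blood remains fill the lumen it appears
*hyper*-intense; where the lumen is an empty void it appears
*hypo*-intense; often both occur along a single vessel. A global intensity
threshold therefore cannot recover the vascular space: either polarity
choice misses the other half.

What *is* consistent is the **boundary** between tissue and vascular
space. vesselmorph segments that boundary with a 3D Deriche–Canny edge
detector and converts the resulting boundary shell into a solid vessel
mask by morphological post-processing. Downstream, skeleton-based
morphometry quantifies the extracted network.

## The segmentation model

The fine-resolution workflow (`segment_fine()`, intended for ~1 µm voxel
data) is, in order:

1. **Dual-scale 3D median filtering** with kernels 7³ and 19³. The small
   kernel preserves capillary-scale structures; the large kernel
   suppresses texture inside large vessels whose edge contrast is weaker,
   so their boundaries survive edge detection. Each filtered volume is
   processed independently.
2. **Deriche–Canny edge detection** (`canny_edges_3d()`): the recursive
   (IIR) Deriche derivative along each axis with Deriche smoothing along
   the other two; non-maximum suppression along the 26-quantized gradient
   direction; hysteresis keeping weak edges (≥ `t_low`) only when
   26-connected to a strong edge (≥ `t_high`).
3. **OR fusion** of the two edge maps (`combine_scales()`).
4. **Post-processing**: island removal (components with physical volume
   *strictly below* 2.5×10³ µm³ are treated as noise; components exactly
   at the threshold are kept), morphological closing (ball, radius 2
   voxels by default — a radius-1 ball is only the 6-neighbourhood and
   cannot seal the corner-touch micro-handles of a noisy edge shell,
   which would survive as thousands of spurious loops in the
   topology-preserving skeleton), and hole filling — in that order.

The coarse-resolution workflow (`segment_coarse()`, ~5 µm voxels) skips
median filtering, and uses a region-grown tissue mask (eroded by one
voxel) to discard the strong tissue–paraffin boundary edges. The
downsampled workflow (`run_pipeline(mode = "downsampled")`) halves the
resolution by cell-centred trilinear averaging, segments with a single 7³
median, masks the circular field-of-view rim, and stitches per-tile masks
by integer phase correlation.

### Automatic hysteresis thresholds

The original workflow's numeric thresholds live in parameter tables that
accompany specific scanner data; this package must choose defaults that
transfer across intensity scales and vessel densities. Rank-based
(quantile) thresholds fail here: the fraction of edge voxels among
non-maximum-suppression survivors depends on how much vasculature the
volume happens to contain, so any fixed quantile lands in the noise mode
for sparse volumes (on a 256³ phantom with ~2 % vessels, a q90 threshold
admits noise ridges everywhere and the mixed-lumen Dice collapses to
≈0.4) and in the edge mode for dense ones.

The default (`threshold_method = "noise_adaptive"`) instead exploits the
shape of the suppressed-magnitude distribution: after median filtering,
noise ridges and structure edges form modes separated by one to two
orders of magnitude. `t_high` is the larger of two scale-free estimates
on the log₁₀ magnitudes — Otsu's threshold, which separates the modes
whenever edges carry appreciable mass, and the decay point of the
dominant noise mode (the first histogram bin right of the global mode
below 1 % of its height with mass remaining beyond it), which keeps the
threshold above the noise floor even when vessel edges are a fraction of
a percent of the survivors and Otsu's split would sink into a broad
noise mode. On a near-noise-free volume the distribution is unimodal
(edges only), the decay point does not exist, and the Otsu term places
the threshold inside the edge mode, which hysteresis connectivity then
recovers in full. `t_low = t_high / 2` is the classic Canny ratio.
Absolute thresholds and quantile thresholds remain available
(`t_low`/`t_high`, `threshold_method = "quantile"`).

### Hole filling for tubes

A 3D hole fill (background components not reaching the volume border)
cannot fill a tubular shell that is open at both ends — its lumen is
connected to the exterior through the tube mouths. Because cross-sections
of such shells are closed rings, the package unions the 3D fill with
per-slice 2D fills along all three axes, which solidifies open tubes at
any orientation. Whether the original workflow filled in 2D or 3D is not
documented; the tri-axial union is this package's documented
interpretation, chosen because it reproduces the intended "remove
cavities within the vascular space" behaviour for clipped vessels.

### Other conventions

* Axis order is `(z, y, x)`, with `z` the TIFF page index. Voxels are
  isotropic; anisotropic data are rejected rather than silently
  mishandled.
* Foreground uses 26-connectivity, background/cavities 6-connectivity
  (the standard dual pair, avoiding topological paradoxes).
* Out-of-volume voxels count as *foreground continuation* for thinning,
  distance transforms and erosion: vessels clipped by the field of view
  are assumed to continue, so their skeletons reach the border and their
  thickness is not artificially reduced there. (A consequence: a mask
  filling the whole volume has no border to erode and does not thin.)
* NMS direction quantization uses the 26 neighbour directions with a
  fixed, documented enumeration order for ties.

## Morphometry

**Skeletonization** (`skeletonize_3d()`) is sequential topology-preserving
thinning: simple, non-endpoint border voxels (Bertrand–Malandain
characterization: one 26-connected foreground component in the
neighbourhood and one 6-connected background component adjacent to the
centre) are deleted in six directional subiterations until stable.
Endpoints (≤ 1 foreground neighbour) are protected, so free vessel ends
keep their full length; loops and connectivity are preserved by
construction.

The one-voxel-wide centerline is decomposed into **nodes** (26-connected
clusters of voxels with degree ≠ 2) and **branches** (chains between
nodes). Three of the package's own choices matter here:

* *Artifact spur suppression.* Terminal spurs shorter than 1.5× the
  local inscribed radius are removed during graph construction: they are
  the traces of surface bumps of the (noisy) segmented mask — a real
  side branch must at least clear its parent's radius.  Skeletons of
  clean phantoms are unaffected; without the rule, the skeleton of a
  segmented mask disintegrates into spur-induced junctions.
* *Junction consolidation.* The junction of thick tubes thins into
  several nearby high-degree voxels joined by short chains that lie
  inside the junction's inscribed sphere. Chains between junction voxels
  shorter than 1.5× the local inscribed radius are absorbed into one
  node, so one anatomical bifurcation is one node. Without this, a single
  bifurcation of ~10 µm vessels contributes two or three spurious
  branches of a few µm that no terminal-branch pruning can remove.
* *Branch length* is the Euclidean polyline length of the voxel chain
  (steps of 1, √2, √3 voxels), not the voxel count, which would
  overestimate oblique tubes by up to 73 %.

**Pruning** (`prune_branches()`) removes, in a single pass, terminal
branches (free tips) shorter than 25 µm. Loop branches and
junction-to-junction branches are never removed; degrees are recomputed
afterwards, so two surviving arms of a pruned Y merge into one branch.

**Local thickness** (`local_thickness()`) follows the
Hildebrand–Rüegsegger definition: the diameter of the largest sphere
fully inside the mask covering each voxel, computed from an exact
Euclidean distance transform (Felzenszwalb–Huttenlocher) followed by
exhaustive inscribed-sphere painting. Sphere radii are centre-to-centre
distances to the nearest background voxel — the convention of the
standard local-thickness plugin implementations this workflow descends
from. That convention reads structures about one voxel wide of their
geometric width (a slab of width w voxels reads exactly w + 1); the
alternative surface-based radii were implemented and measured during
development but under-read thin *oblique* tubes by up to 1.5 voxels,
because the digitized boundary of an oblique tube brings background
voxels diagonally close to the axis. At the capillary scale the
convention choice is a one-in-ten relative effect and is stated here so
diameters can be compared across tools. The diameters are *outer*
diameters of the segmented space — for real vessels, lumen plus wall.

**Diameter distributions** (`diameter_distribution()`) sample the
thickness map at every skeleton voxel and bin with 1.6 µm bins anchored
at 0 (the bin width implied by reporting a modal class of 8.6–10.2 µm).
Per-branch mean diameters exclude skeleton voxels within 1.5× the local
inscribed radius of a branch end: the crotch of a junction admits
inscribed spheres much larger than either branch, and without the
exclusion a thin child branch attached to a thick parent is biased
upward by 10–15 %.

**Densities.** Vessel volume fraction is `100 · |mask ∩ roi| / |roi|`.
Vessel length density is

&nbsp;&nbsp;&nbsp;&nbsp;`L / (V · s²)` → reported in mm/mm³,

with `L` the total pruned skeleton length, `V` the tissue volume and `s`
the linear shrinkage factor estimated as the cube root of the
post/pre-embedding volume ratio (`estimate_shrinkage()`). Note the
direction: dividing by `s² < 1` makes the corrected density *larger* than
the uncorrected one. The geometric reading (lengths shrink linearly with
`s`, volumes with `s³`, so the density of the original tissue is the
measured `L/V` multiplied by `s²`… or divided, depending on whether mask
lengths or tissue volumes are taken as already shrunken) is genuinely
ambiguous; the package implements the formula exactly as printed in the
workflow it reproduces and exposes `s` as an explicit parameter, so
either convention can be obtained.

## Vessel classification

`geodesic_select()` implements morphological reconstruction by dilation —
the union of 26-connected vessel components intersecting a seed region —
used with anatomical seeds (e.g. the intercollicular sulcus selects
central collicular vessels, the collicular surface peripheral ones).
Components reached from both seeds are labelled central (fixed precedence)
and flagged ambiguous rather than silently resolved.
`classify_short_long()` calls a component *long* iff it has a voxel
within `tolerance_vox` (default 2, robust to border erosion) of a named
far face of the field of view. `max_inscribed_diameter()` is twice the
maximum distance-to-background over the component, and the short/long
populations are compared with a pooled-variance Student t-test
(`two_sample_ttest()`; Welch's correction can be had directly from
`stats::t.test()` if variances differ strongly). `sample_qc_voxels()`
draws a seeded uniform sample of mask voxels (default 100) with
orthogonal image patches for manual false-positive review — the visual
judgement itself stays with the human.

## The phantom generator

`generate_phantom()` renders tubes (polyline centerlines, per-tube radii,
optionally linearly tapering) into noisy tissue. A voxel is vessel iff
its centre lies within the local radius of a centerline — a rule chosen
so analytic volume checks are clean. The contrast model mirrors the
target data: tissue 120, bright lumen 200, dark lumen 40 on an 8-bit
scale (symmetric ±80 contrast, so neither lumen polarity is favoured),
Gaussian noise with SD 16 — a contrast-to-noise ratio of 5 — and the
bright/dark split laid out as one contiguous arclength block per tube
(`lumen_bright_fraction`), mirroring real vessels where a stretch with
blood remains adjoins a void stretch. An optional Gaussian blur and an
optional single bright/dark fringe ring pair (off by default) emulate the
point spread and phase-contrast edge enhancement; no quantitative
phase-propagation model is attempted. Volumes are rounded to integers in
[0, 255] as scanner exports are. Geometry and noise are decoupled: the
truth mask depends only on the tubes, every random draw flows through one
recorded seed, and `branching_tree_spec()` grows a random bifurcating
tree (≤ 2 children per endpoint, siblings ≥ 35° apart so junctions stay
clean) with diameters drawn from a user-set population.

What the phantom does *not* emulate: reconstruction artefacts (rings,
streaks), spatially correlated noise, red-blood-cell-scale texture,
vessel wall layering, or anisotropic point spread. Passing phantom tests
therefore demonstrates the geometric and numerical correctness of the
pipeline and its polarity robustness, not performance on any particular
scanner's data.

## Problem sizes and numerical choices

The test suite exercises the full pipeline at the sizes where its
behaviour is interesting but still quick to verify: oracle equivalences
(median vs exhaustive median, recursive Deriche vs FIR convolution at
relative RMS ≤ 10⁻³, flood fills, inscribed spheres) on 16³–32³ volumes;
polarity robustness on a fixed 256³ tree phantom at contrast-to-noise 5;
morphometry recovery on a hand-constructed ten-tube phantom (radii
4.7–23.5 µm) at 256³; split-then-stitch consistency on a 256×192×192
volume halved into overlapping tiles. `scripts/acceptance.R` re-runs the
same computations at 192³/256³ from a fresh seed.

Smaller numerical decisions, for the record: Deriche recursions are
initialised at their constant steady state with ⌈12/α⌉ voxels of
reflected padding, so a constant volume yields an exactly zero gradient;
gradient magnitudes below 10⁻⁹ of the intensity range are treated as
round-off; the 3D median uses an exact running-histogram algorithm on any
integer lattice (including the 1/8-step lattice produced by
`downscale_half()`) and falls back to exhaustive per-voxel medians
otherwise; stitching is translation-only at integer-voxel precision with
the offset defined by `tile_b[v] = tile_a[v + offset]`; float TIFF output
is stored as 32-bit samples rescaled to [0, 1] with the original range in
the JSON sidecar (the `tiff` package does not write IEEE-float samples),
which round-trips to ~2×10⁻¹⁰ relative — integer TIFFs round-trip
bit-exactly.

## Known limitations

* Stitching has no subvoxel or rotational refinement.
* Thinning is sequential; skeleton details (not topology) can depend on
  the scan order, which is fixed and deterministic.
* The edge detector assumes boundaries are locally step-like after median
  filtering; heavy phase-contrast fringes (strong bright/dark halos) will
  place the edge at the fringe rather than the interface, biasing
  diameters by up to the fringe width.
* Junction consolidation at 1.5× the inscribed radius can merge two real
  junctions closer than that scale — acceptable for vascular trees, wrong
  for dense lattices.
* Sub-resolution tubes (radius < 1 voxel) are rasterized but flagged;
  their morphometry is not meaningful.
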