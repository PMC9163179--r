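# vesselmorph

Edge-based 3D vessel segmentation and vascular morphometry for
phase-contrast X-ray microtomography (PC-µCT) of unstained tissue.

## The problem

PC-µCT resolves the microvasculature of unstained, paraffin-embedded
tissue without contrast agents, but the former vascular space has no
consistent intensity: stretches filled with collapsed vessel walls or
blood remains are *hyper*-intense, empty stretches are *hypo*-intense,
often within one vessel. Intensity thresholding therefore cannot recover
the vasculature — either polarity choice misses the other half. What is
consistent is the *boundary* between tissue and vascular space.

vesselmorph is for image analysts working with volumetric scans of
microvasculature (brain stem and similar soft tissue) who need a
reproducible, scriptable pipeline from a raw TIFF stack to vascular
morphometry, plus a synthetic phantom generator that makes every stage
testable with exact ground truth.

## The method

Segmentation detects vessel boundaries and solidifies them:

1. dual-scale 3D median filtering (7³ preserves capillaries, 19³
   preserves large vessels with weak edge contrast);
2. Deriche–Canny edge detection per scale: recursive Deriche gradient
   `∇I = (∂z, ∂y, ∂x) * I`, non-maximum suppression along the 26-quantized
   gradient direction, hysteresis thresholding (`t_low`, `t_high` chosen
   per volume, scale-free);
3. logical OR of the two edge maps;
4. island removal (components < 2.5×10³ µm³), morphological closing,
   hole filling.

Morphometry on the binary mask `V` inside a region of interest `T`:

- vessel volume fraction `= 100 · |V ∩ T| / |T|` (%);
- topology-preserving 3D thinning → centerline skeleton, branches pruned
  below 25 µm;
- vessel length density `= L / (|T| · s²)` in mm/mm³, with `L` the total
  skeleton length and `s` the linear tissue shrinkage factor
  `s = (V_after / V_before)^(1/3)` from pre/post-embedding volumes;
- local thickness (largest inscribed sphere, Hildebrand–Rüegsegger) at
  every skeleton voxel → diameter histograms (1.6 µm bins);
- geodesic reconstruction from anatomical seed regions → central vs
  peripheral vessel classes; short/long split by field-of-view reach;
  maximum inscribed-sphere diameters compared with a Student t-test;
- seeded random QC voxel samples for manual false-positive review.

## Worked example

Generate a noisy mixed-polarity phantom with known geometry, segment it,
and quantify the result:

```r
library(vesselmorph)

spec <- branching_tree_spec(n_branches = 5, diameter_set_um = c(9.4, 18.8),
                            rng_seed = 7, shape = c(160, 160, 160),
                            voxel_size_um = 0.94,
                            branch_length_um = c(60, 80),
                            lumen_bright_fraction = 0.5)
phantom <- generate_phantom(spec)
phantom$truth
#> <phantom_truth> 5 tube(s), total length 262.7 um, vessel volume 3.482e+04 um^3

mask <- segment_fine(phantom$volume)
mask
#> <binary_mask> 160 x 160 x 160 (z, y, x), voxel 0.94 um
#>   38580 foreground voxels (0.942% of volume, 3.204e+04 um^3)
mask_dice(mask, phantom$truth$vessel_mask)
#> [1] 0.935

skel  <- prune_branches(skeletonize_3d(mask), 25)
skel
#> <skeleton_graph> 248 voxel(s), 7 branch(es), 7 node(s), total length 314.9 um
thick <- local_thickness(mask)
dist  <- diameter_distribution(skel, thick)
dist$mode_bin_um
#> [1] 8.0 9.6

roi <- binary_mask(array(TRUE, dim(mask$data)), mask$voxel_size_um)
vessel_volume_fraction(mask, roi)
#> [1] 0.9416504
vessel_length_density(skel, sum(roi$data) * voxel_volume_um3(roi), 0.8)
#> [1] 144.5841
```

The phantom mixes hyper- and hypo-intense lumen stretches
(`lumen_bright_fraction = 0.5`) at a contrast-to-noise ratio of 5; the
edge-based mask still overlaps the ground truth at Dice 0.935, where a
global Otsu threshold reaches only ~0.03 on the same volume
(`segment_global_threshold()`). The modal diameter bin (8.0–9.6 µm)
brackets the planted 9.4 µm capillary population, and the per-branch
table (`dist$branch_table`) recovers the 9.4/18.8 µm branch diameters to
within a voxel.

Volumes read/write as multipage TIFF with a JSON sidecar
(`read_volume()`, `write_volume()`); full workflows — fine, coarse and
downsampled-with-stitching — run from a YAML/JSON config via
`run_pipeline()`, and `inst/scripts/vesselmorph.R` wraps the same
functions for shell use.

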