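---
title: "Methods: from cleared-brain volumes to atlas connectivity"
author: "clarityatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from cleared-brain volumes to atlas connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clarityatlas)
```

`clarityatlas` implements the computational core of a multimodal
cleared-brain analysis workflow: estimating axonal fiber orientation from
3D structure tensors and tracking streamlines through it, mapping where
those streamlines terminate, segmenting stained cells and summarising them
per hierarchical atlas region, interrogating projection-connectivity
tables for the regions inside a lesion, localizing cut tissue sections
inside whole-brain volumes, and the group-level statistics tying these
modalities together. This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic phantoms do and
do not establish.

## Geometry conventions

A `voxel_grid` stores a 3D array with voxel spacing and origin in
micrometres and a three-letter anatomical axis code (e.g. `"RAS"`). Voxel
indices are 1-based; the world position of voxel `(i, j, k)` is
`origin + (index - 1) * spacing` along each axis, and points are assigned
to the voxel with the nearest centre. NIfTI headers carry millimetres and
are converted on the way in and out. These conventions are applied
uniformly: streamlines, landmark sets and object centroids are always in
world micrometres.

## Structure-tensor orientation estimation

Image intensity gradients mark the walls of fluorescently filled fiber
bundles. The local fiber direction is therefore the direction of *least*
intensity variation: the tertiary eigenvector (smallest eigenvalue) of the
structure tensor

$$ S_w(p) = \int w_{\sigma_g}(r)\, \nabla I(p-r)\, \nabla I(p-r)^{\top}\, dr, $$

where the gradients are computed with first-order derivative-of-Gaussian
filters of standard deviation $\sigma_{\mathrm{dog}}$ and $w$ is a
Gaussian of standard deviation $\sigma_g$ smoothing the six unique
components of the gradient outer product. Both scales are in micrometres
and converted to voxels per axis, so anisotropic voxels are handled. The
discrete derivative kernels are normalised so a unit ramp has derivative
exactly one, which makes the analytic ramp tests exact; the smoothing
kernels are sum-normalised. All separable convolutions use replicate
boundaries.

Defaults are $\sigma_{\mathrm{dog}} = 1\,\mu m$, $\sigma_g = 2\,\mu m$ at
unit voxel size, i.e. one and two voxels. Two practical rules emerged from
the tube-phantom experiments:

* orientation accuracy inside a bundle is insensitive to $\sigma_g$ in the
  2–4 voxel range (100% of in-tube voxels within 10° of the true axis at
  a contrast-to-noise ratio of 8);
* *tracking* stability is not: streamlines integrate small orientation
  biases over hundreds of steps, and an integration scale at or above the
  bundle radius ($\sigma_g \approx 4$ voxels for a radius-3 tube) is
  needed for drift-free end-to-end tracking. The along-tract tests use
  that setting.

Voxels whose tensor trace is zero up to round-off (the floor is scaled by
the mean squared image intensity, so a constant image is entirely
invalid), or falls below `coherence_min` times the maximum trace, carry no
orientation.

## FACT streamline tracking

Tracking is deterministic fiber assignment by continuous tracking:
streamlines start at the centres of the seed-mask voxels (lexicographic
order, capped at 5000, deterministically subsampled via `seed_density`)
and are propagated bidirectionally with a fixed step (default half the
smallest voxel size) along the orientation of the containing voxel.
Orientations are axial, so each step first flips the vector to best align
with the previous direction; a streamline terminates when

1. the aligned turn exceeds `alpha_thresh_deg` (default 35°),
2. it leaves the brain mask,
3. it enters a voxel without a valid orientation, or
4. it exceeds `max_length_um` (when infinite, a cap of four bounding-box
   diagonals guards against closed orbits).

The angular threshold is the only anisotropy gate: in unstained or noisy
tissue the tensor orientation decorrelates between voxels, every step
looks like a sharp turn, and tracks stop — the analog of an FA threshold
in diffusion tractography. The classic exit-point formulation of FACT is
replaced by fixed sub-voxel stepping with nearest-voxel orientation
lookup; at half-voxel steps no voxel can be skipped, which keeps the
tract-density definition below exact.

## Tract density, terminal maps, and passing vs terminating fibers

The tract-density value of a voxel is the number of *distinct*
streamlines visiting it; the terminal map counts streamline endpoints, so
it sums to exactly twice the number of streamlines before masking. Since
viral tracer fills axons from an injection site, endpoints cluster both at
the injection (proximal spill-over) and at true projection terminals. The
injection cluster is removed by binarizing the terminal map (counts > 0 by
default), labelling 26-connected components, and zeroing the largest
component, which must intersect the seed mask — otherwise the largest
seed-intersecting component is removed instead, with a warning.

Per-region connectivity weights follow the two complementary definitions:
*passing* weight is the mean tract density over the region's voxels;
*terminal* weight is the sum of (masked) terminal counts inside it.
Terminating streamlines are by construction a subset of passing ones.
Ranking ties are broken by ascending region id.

## Cell segmentation

The protocol mirrors a stack-based clearing workflow tuned for sparse
neuronal (YFP) and dense nuclear (PI) stains:

1. per-slice background removal with a rolling window of radius 50 px,
2. histogram matching of every slice to the first slice,
3. percentile contrast stretch to [0, 1],
4. 3D median filtering with radius 2 px (skipped for PI, where cell
   density makes it counterproductive),
5. Phansalkar local thresholding with a 15 px disc: foreground iff
   $v > m\,(1 + p e^{-q m} + k(s/r - 1))$ with local mean $m$ and
   standard deviation $s$, constants $k = 0.25$, $r = 0.5$, $p = 2$,
   $q = 10$ (the standard published values),
6. markers = 26-connected components of the 3D local minima (radius 2 px)
   of the inverted image inside the foreground,
7. marker-controlled 3D watershed (26-connectivity, priority-flood)
   flooding the inverted image within the foreground mask,
8. removal of objects outside `[min_object_volume_px,
   max_object_volume_px]`.

Implementation notes and deliberate deviations:

* The rolling-ball background is approximated by grayscale opening with a
  separable square window of half-width 50 px, computed on a lightly
  (3×3) pre-smoothed slice. Without the pre-smoothing the opening tracks
  the *lower envelope* of the noise, roughly 3 noise-SD below the true
  background, and the residual sabotages local thresholding; rolling-ball
  implementations pre-smooth for the same reason.
* The contrast stretch saturates 0.35% of voxels at the dark tail but
  only 0.005% at the bright tail. When stained objects occupy under ~1%
  of the volume, a symmetric 0.35% cut falls *inside* the signal and
  rescales the background upward by a factor of ~2, which breaks the
  Phansalkar criterion; the bright-tail guard is only there for hot
  pixels.
* `min_object_volume_px` defaults to 0 (the original protocol filters
  only large objects). For the blob phantom the validation analyses use
  half the smallest expected cell volume (100 px for blobs of σ ≈ 2 vox),
  the usual practice for rejecting noise specks.
* The Phansalkar disc radius is clamped to fit inside a slice.

Validation matches object centroids to ground-truth centres greedily,
nearest pair first, one-to-one, within `match_radius_um`. Specificity is
TP/(TP+FP) and detection rate TP/(TP+FN). On the default blob phantom
(200 Gaussian blobs, contrast-to-noise 8, a 30% linear background ramp)
both are 1.0 at seed 1 and ≥ 0.95 across seeds.

The brain mask for whole-volume work is Otsu thresholding, erosion,
retention of the largest 26-connected component, and dilation.

## Voxelization and regional features

Centroid-mode voxelization adds one count to the coarse (atlas-resolution)
voxel containing each object's centroid and conserves the total count
exactly; it is the default. Kernel mode implements the spherical-kernel
description verbatim — per coarse voxel, the number of distinct object ids
intersecting a sphere of `kernel_radius_um` (default 5 µm) at the voxel
centre — and is *not* conserving, since an object can intersect several
spheres; both radius and mode are parameters because a 5 µm kernel on a
25 µm atlas grid cannot tile space. Regional feature tables report
object counts, densities (count per mm³ of region volume *measured from
the label volume*, not from ontology metadata), and mean intensities.

Degeneration flagging normalizes each case region's density by the mean
control density, reports the reciprocal as the degeneration score, and
flags regions more than two standard deviations below the mean normalized
density of the evaluated population (the ipsilateral targets of the
report at hand). The statistic is scale-invariant by construction.
Lesion incidence maps sum binarized subject masks; the consensus mask
keeps voxels above a fraction (default one half) of the cohort.

## Atlas ontology and label volumes

The ontology is a single-rooted structure graph with per-node depth
(root = 0) and order (depth-first traversal index). Flat-record JSON in
the Allen dialect loads through an alias table
(`parent_id`/`parent_structure_id`, `graph_depth`/`depth`/`st_level`,
...), defaulting to the depth-style field where both exist — the two
published conventions disagree and the choice is configurable.
`collapse_to_depth()` groups fine labels into their unique ancestor at a
target depth; `collapse_up_levels()` provides the "grand-parent" (two
levels up) convenience. Cycles, duplicate ids and orphan parents are load
errors. `labels_in_mask()` ranks the regions inside a mask by in-mask
voxel count, ties by ascending id — used to pick the largest N labels
inside a lesion.

## Connectivity interrogation

Connectivity tables are CSVs with one row per (experiment, target):
injection structure and volume, target structure, hemisphere tag, strain,
projection volume, and normalized projection volume (projection volume
divided by tracer volume in the injection structure; consistency is
checked on load). The wild-type strain filter (`C57BL/6J`) is on by
default. Records without a hemisphere tag are treated as ipsilateral with
a warning.

`find_injection_experiment()` searches the label itself, then its
ancestors nearest-first, for an experiment-bearing structure — so every
fine label inherits the nearest available injection. `ranked_targets()`
sorts targets by decreasing normalized projection volume after removing
(a) structures with graph depth < 5 or graph order < 6 (keeping
mid-ontology detail structures), (b) descendants of the injection site,
and (c) optionally, structures overlapping a lesion mask. Tie-breaking is
uniform everywhere: weight desc → frequency desc → mean weight desc → id
asc. `common_targets()` ranks by the number of injections listing a
target. Graph export writes node-link JSON with links below a threshold
dropped.

## Part-to-whole section localization

A cut section is located inside the whole volume by a coarse-to-fine
similarity search. The similarity is the mean squared difference between
the section and a candidate segment after z-scoring both patches, which
makes the match robust to the intensity inhomogeneity that clearing and
imaging introduce (`raw_msd = TRUE` disables the normalization). The
returned segment is expanded 15% per axis to absorb boundary errors
in the subsequent deformable registration, which is out of scope here.

The search schedule required three design decisions beyond the sliding
window/decreasing-increment outline, each driven by planted-crop
experiments:

* **Tiling density.** With tiles at full section stride the worst-case
  misalignment is half a section, far wider than the similarity basin of
  realistic texture, and the search missed 30–50% of planted crops. The
  tiling round uses a stride of one third of the section size.
* **Pyramid scoring.** Each round scores candidates on data low-passed to
  that round's stride scale (σ = stride/2 per axis), so the basin is
  always wider than the grid; the *reported* offset and similarity always
  track the raw metric, and the incumbent is rescored every round, so
  the best reported similarity is non-increasing across rounds — an
  invariant the tests check.
* **A small beam.** A single incumbent occasionally locks onto a remote
  look-alike ranked just above the true basin at the coarsest level.
  Four well-separated incumbents are carried between rounds; the answer
  is still the single best raw-MSD offset.

Strides halve each round (floor, minimum 1), ties prefer the
lexicographically smallest offset, and an all-constant section is
rejected as degenerate. On a 100³ two-scale textured phantom, exact crops
are recovered with similarity 0 and noisy crops (SNR 10) within 2 voxels
for 20/20 random plants across texture seeds.

## Group statistics

* **Heat-maps** are literal voxelwise sums of squares across subjects; an
  RMS mode is available for display comparability but is not the
  definition.
* **Label-wise paired t-tests** (two-sided) compare ipsilateral and
  contralateral per-region features across subjects. Identical
  hemispheres give t = 0, p = 1; a zero-variance nonzero difference is
  reported as degenerate rather than given a fabricated p. The painted
  map assigns each label's voxels its p-value, with labels above the 0.05
  display threshold set to 1. No multiplicity correction is applied by
  default, matching the display-threshold convention of the original
  analysis.
* **Voxelwise Spearman correlation** between two maps supports masking,
  exclusion masks (e.g. ventricles), per-hemisphere normalization by the
  contralateral mean, and Gaussian pre-smoothing (σ = 1 voxel) absorbing
  registration error. P-values come from `stats::cor.test` (exact for
  small tie-free samples, asymptotic otherwise).
* **Landmark TRE** matches landmarks by name and reports per-pair
  distances and their RMS in micrometres.

## Tract profiles and hemisphere asymmetry

Profiles resample each streamline to `n_nodes` (default 100) equal
arc-length nodes, sample intensity by trilinear interpolation, and average
bundles of ten adjacent streamlines; adjacency means consecutive in seed
order, which under deterministic lexicographic seeding tracks spatial
adjacency (a nearest-neighbour chaining sort could replace it; seed order
was chosen as the simpler, fully deterministic rule). Contralateral
profiles use the mirrored-volume convention: the intensity volume is
flipped left-right so the *same* streamline geometry samples the opposite
hemisphere.

Per subject, asymmetry is the mean over nodes of
$|c_n - i_n| / \overline{c} \times 100$ (the signed per-node variant is
also returned), and groups are compared with a two-sided two-sample
Student's t-test on the per-subject values. The statistic is exactly zero
under mirror symmetry, exactly $f \times 100$ for a planted fractional
loss $f$, and invariant to global intensity scaling — all tested.

## Synthetic phantoms

All generators are pure functions of their arguments and seed
(Mersenne-Twister with inversion sampling, pinned), and every phantom
returns its ground truth so no test re-derives truth from data.

* `make_tube_phantom()`: straight, curved or branching bright tubes with
  Gaussian noise; centerlines and tangents in world µm. Emulates filled
  fiber bundles; does not emulate fiber crossings, multiple orientations
  per voxel, or light-sheet stripe artifacts.
* `make_blob_phantom()`: Gaussian blobs at Poisson-disc centres, linear
  background ramp, Gaussian noise at a set peak SNR. The default volume
  is 192×192×48 so the protocol's fixed 50 px rolling radius is smaller
  than the slice, and blobs span the full z extent so every slice of the
  stack carries signal — as real stacks do, and as the first-slice
  histogram reference requires. It does not emulate anisotropic nuclei,
  intensity-correlated clustering, or optical attenuation with depth.
* `make_toy_atlas()`: a binary-split hierarchy (first split = left/right)
  to depth ≥ 6 with its leaf-label volume and a synthetic projection
  table in the documented CSV schema.
* `make_asymmetric_pair()`: a mirror-symmetric smooth volume whose right
  hemisphere is attenuated by a known fraction inside a planted mask,
  plus its exact left-right flip.

Passing the phantom-based tests shows the algorithms are correct on data
matching their assumptions; it does not show robustness to real-tissue
effects the phantoms omit (registration error, staining variability,
crossing fibers, optical artifacts).

## Problem sizes and runtime choices

The validation analyses run at desk scale by design: 64³ tube phantoms,
192×192×48 blob fields with 200 cells, 100³ search volumes with ~30³
sections, 127-node toy ontologies, and 200 Monte-Carlo repeats for the
asymmetry power check. These sizes keep the full suite within a couple of
minutes on one CPU while leaving every statistic far from its decision
boundary.

## Known limitations

* Single fiber orientation per voxel; no crossing-fiber model.
* Kernel-mode voxelization is quadratic in the kernel/voxel ratio and
  intended for small kernels.
* The deformable registration steps surrounding the pipeline (template
  alignment, section-to-segment warping, bias-field correction) are
  external tools by design; only their quantitative bookkeeping
  (landmark TRE, section search) is implemented here.
* TIFF output rescales intensities to 16-bit; NIfTI is the lossless
  round-trip format.
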