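---
title: "Measuring long-bone lengths from micro-CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring long-bone lengths from micro-CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteobox)
```

## The problem

Skeletal phenotyping in developmental biology routinely needs the lengths of
the long bones (humerus, radius, ulna, femur, tibia, clavicle) of many
specimens — wild-type versus mutant, treated versus control — with effect
sizes down to a few percent. Whole-body micro-CT preserves the specimen and
scans batches quickly, but turning a reconstructed volume into per-bone
lengths by hand (thresholding, clicking surfaces, placing calipers on a 3D
render) is slow and operator-dependent. osteobox automates that path: the
only per-specimen human input is one seed voxel per bone of interest, and
everything downstream — segmentation, labelling, measurement, batch
statistics — is deterministic code.

## Pipeline model

The pipeline assumes mineralised bone is the densest material in the scan,
so a single **global lower threshold in Hounsfield units** separates bone
from soft tissue and air. Two ways to choose it are provided:

* **Presets** per developmental stage (`preset_threshold()`): the shipped
  table covers P7 and E17.5 at low/medium/high levels in two profiles
  (Mimics-style: 650/398 HU for P7, 398/226 HU for E17.5; BoneJ-style:
  500/385 and 400/280 HU). These are empirical values for uncalibrated
  lab scanners; the table is configuration, not a constant, because the
  exact GV-to-HU mapping differs per scanner and reconstruction kernel.
  The `medium` entries are the midpoints of each stage's low/high pair so
  that low < medium < high always holds; override them freely via
  `options(osteobox.presets = ...)`.
* **Maximum-entropy selection** (`max_entropy_threshold()`): Kapur's
  criterion on a 256-bin histogram of the full stack — the split `t` that
  maximises the sum of Shannon entropies of the renormalised background
  and foreground distributions. Natural logarithms, `0·log 0 := 0`, only
  splits with both class probabilities positive are considered, and ties
  break to the lowest qualifying split. 256 bins is the ImageJ convention
  for data deeper than 8 bits; the returned threshold is the lower edge of
  the first foreground bin, in HU.

Thresholds are always **inclusive at the lower bound**, and thresholding is
applied to raw (unresampled) voxels.

Young bones are porous and neighbouring elements lie close together
(radius/ulna, tibia/fibula), so the raw mask is refined slice by slice —
the 2D versions of the classic tools, in this order:

1. `fill_holes_2d()` — background not connected to the slice border
   becomes foreground (closes the marrow cavity).
2. `remove_outliers_2d()` — per-slice area opening deletes components
   below `min_retained` px (default `ceil(pi * radius^2)` with
   radius = 2 px). Components of exactly the floor area survive; removal
   is strictly below. This is an area-opening re-interpretation of the
   usual despeckling step: the input here is already binary, so a rank
   filter would be both slower and less predictable.
3. `erode_2d()` — 3x3 box erosion; `n` then `m` iterations equals `n+m`.
4. `watershed_separate_2d()` — per slice, Euclidean distance transform,
   regional maxima merged within a 0.5 px plateau tolerance, marker flood
   by descending distance, 1-px cut lines between basins. This is what
   separates near-touching parallel bones whose blurred interface
   survives thresholding. We claim the separation behaviour, not pixel
   parity with any particular GUI tool's internals.

3D connected components (`label_components_3d()`) default to
26-connectivity (configurable to 6; the upstream tools never document
theirs), labelled deterministically by first encounter in column-major scan
order. `filter_by_volume()` then removes debris below a volume floor whose
default is 1000 voxels at 20 um, scaled by voxel volume so the physical
floor (8e6 um^3) is resolution-independent — small enough that a clavicle
survives, large enough that ossification specks do not.

### Landmarks instead of clicks

A landmark file (one row per bone: name, side, present flag, seed voxel)
replaces the interactive select/skip loop. `assign_labels()` resolves each
present seed to its component; a seed on background is an error naming the
bone (the non-interactive analogue of a re-prompt). When two landmarks
resolve to one component — the fused tibia+fibula case — the element is
flagged **composite**, measured as-is under the joined name
(`TIBIA+FIBULA`), and excluded from intra-limb ratios. Accepting the fusion
is deliberate: the protruding member biases the composite length by a
consistent amount, which cancels in left/right comparisons, whereas forcing
a split injects operator-dependent geometry. For the cases worth splitting
(radius/ulna), `split_component()` provides a seeded 3D marker watershed on
an erosion-depth distance transform; it conserves voxels up to the 1-voxel
cut and keeps each seed group in its own part, but it is an algorithmic
approximation of manual mask splitting, not a reproduction of it.

## Length from the inertia tensor

Each labelled bone is treated as unit point masses at voxel centres. The
inertia tensor about the centroid,

$$ T = \sum_v \left[ (r_v \cdot r_v)\, I_3 - r_v r_v^{\top} \right], $$

gives principal axes as eigenvectors; the axis of the **smallest** moment
is the long axis of an elongated bone. Per-voxel cuboid self-inertia is
omitted: it adds a constant diagonal term that cannot change the
eigenvectors' ordering at bone scale. Axes are made deterministic (largest
component positive, right-handed triple), and a component whose three
moments are equal within tolerance (sphere, cube, single voxel) is flagged
degenerate and measured along the grid axes rather than along an arbitrary
eigenbasis.

The **aligned box** projects the eight corners of every surface voxel onto
the three axes; the extents are the min/max projections, and the length is
the extent along the long axis. Corners (not centres) are used so that
axis-aligned shapes and single voxels recover exact physical edge lengths.
The **maximum Feret diameter** — the largest pairwise distance over the
same corner points — is computed as a comparator: for oblique rods it picks
a body diagonal and systematically exceeds the aligned-box length, which is
why it is reported but not used as the primary estimator. The Feret
computation prunes candidates with 2D convex hulls in coordinate planes (a
3D hull vertex must be a 2D hull vertex of its coplanar group, so the
pruning is exact) before the pairwise maximum. A best-fit ellipsoid
estimator is deliberately absent: its long axis runs past the bone ends.
The proprietary line-fit measurement used by commercial pipelines is also
not re-implemented — its internals are undocumented and its known bias
(the fitted line need not parallel the main axis) is not something worth
reproducing; the aligned box is the primary estimator here.

All lengths are computed in micrometres from the voxel spacing and reported
in millimetres.

## Reporting

`export_csv()` writes the one-line-per-bone dialect `"RIGHT HUMERUS,7.415"`
(three decimals) used by downstream merge scripts, plus a tidy CSV with
full metadata. `merge_and_clean()` drops non-canonical rows, sorts
alphabetically by `"SIDE BONE"`, and binds batches. Three statistics
summarise batches:

* `lr_ratio()` — left/right length per bone; 1 for a symmetric skeleton,
  the readout for asymmetry phenotypes.
* `intralimb_ratio()` — humerus/radius and femur/tibia per side, the
  normalisation available when contralateral bones are missing.
* `cv_across_batches()` — 100·SD/mean per bone across repeated scans.
  Sample SD (n−1) by default: with three batches the choice is material,
  so it is explicit and switchable (`sd_type = "population"`).

## The phantom generator

Validation runs on synthetic volumes with analytic ground truth, because no
measurement on a real scan has a knowable true length. Bones are
**capsules** (cylinder + hemispherical caps): end-to-end length is
unambiguously `axis + 2·radius`, and the rounded ends exercise the same
half-voxel conventions as real epiphyses. Materials are painted at voxel
centres *before* Gaussian blur (bone 800 HU, soft tissue 50 HU, air
−1000 HU by default — mid-range values of the density bands involved), so
partial-volume voxels fall between tissue and bone HU and measured length
becomes threshold-dependent, reproducing the lower-threshold-longer-bone
sensitivity seen in real data. Additive Gaussian noise (HU) follows, under
a mandatory seed: a fixed spec is bit-reproducible.

Generators: `make_oblique_capsule()` (one bone, arbitrary orientation,
grid sized to the oriented bounding box plus a 3σ blur margin),
`make_limb_pair()` (exactly mirrored placements; ground-truth L/R ratio
`1 − asymmetry/100` exactly, covering the ~5–20% range of interest for
asymmetry models), `make_fused_pair()` (parallel capsules at a programmable
surface gap, fusing when blur reaches the gap, with optional distal
protrusion), and `make_body_phantom()` (12 bones at fixed body-plan slots
with small per-bone tilts, mirrored exactly across the mid-sagittal voxel
plane, plus debris specks for the filters to remove). Body-plan lengths
(1.6–3.4 mm) are late-embryonic mouse scale, chosen so a whole body fits a
desk-scale grid.

What the phantoms do **not** emulate: trabecular texture, growth-plate
cartilage, beam hardening, ring artifacts, or scanner-specific noise
spectra. Passing phantom tests therefore demonstrates geometric and
statistical correctness of the pipeline — discretisation error bounds,
ratio identities, filter behaviour — not robustness to every scanner
artifact; threshold presets still need empirical tuning per instrument.

## Numerical choices and degenerate inputs

* Histogram: equal-width bins over `[min, max]`, rightmost bin closed; a
  constant volume occupies one bin and threshold selection rejects it
  ("degenerate histogram").
* Kapur ties break to the lowest qualifying split (documented, tested).
* Inertia degeneracy tolerance: relative eigenvalue spread < 1e-9.
* Erosion-depth distance (successive 26-neighbour erosions) stands in for
  the Euclidean distance transform inside `split_component()`; it is
  coarser but monotone in depth, which is all the marker flood needs.
* DICOM slice gaps beyond 1% of the median increment are an error naming
  the offending positions; missing rescale tags warn and default to
  slope 1/intercept 0 (uncalibrated scanners are the common case).
* Raster stacks without a spacing sidecar are a hard error — lengths are
  physical, so spacing can never be guessed.
* Binning (`downsample_binning()`) is a block mean that drops trailing
  partial blocks with a message and preserves the mean of the retained
  region to 1e-9.

## Problem sizes used in the shipped validation

The test suite and the acceptance script regenerate all inputs at run
time: mirrored pairs and body phantoms at 20 um spacing (about 1–8 million
voxels per volume), 50 random-orientation capsules of 3–8 mm for the
length-recovery sweep, 1000 random histograms for the threshold oracle,
and three noise re-instantiations of the body phantom for the CV check.
These sizes were chosen to exercise every code path at full working
resolution while a complete run stays comfortably on a laptop.

## Known limitations

* Bent or severely distorted bones: a straight-box length under-represents
  a curved centreline; curved-axis measurement is out of scope.
* Composite elements are only flagged, never auto-split; the seeded
  splitter exists but is operator-initiated.
* Degenerate (near-spherical) components are measured along grid axes and
  flagged rather than oriented.
* The DICOM reader covers explicit-VR little-endian single-frame series —
  the common reconstruction-export case — not the full standard.
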