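# osteobox

Semi-automated measurement of long-bone lengths from whole-body micro-CT
volumes, for skeletal-development labs that need per-bone lengths across
many specimens with minimal operator input and no operator bias.

Given a reconstructed volume (DICOM series or TIFF stack with physical
voxel spacing) and one seed voxel per bone of interest, osteobox:

1. segments mineralised bone with a single global Hounsfield threshold —
   stage-specific presets or Kapur maximum-entropy selection on the stack
   histogram;
2. refines the mask slice by slice (fill holes, remove small specks, 3x3
   erosion, distance-transform watershed) so near-touching elements such
   as radius and ulna separate;
3. labels 3D connected components, drops debris below a volume floor, and
   resolves each landmark seed to its component (fused elements are
   flagged composite, e.g. `TIBIA+FIBULA`, and measured as one);
4. measures each bone from the **minimum bounding box aligned with the
   principal axes of its inertia tensor**: with unit mass at each voxel
   centre, T = Σ[(r·r) I − r rᵀ] about the centroid, the eigenvector of
   the smallest moment is the long axis, and the bone length is the
   extent of the surface-voxel corners along it. The maximum Feret
   diameter (largest pairwise surface distance) is reported as a
   comparator — for oblique rods it picks a diagonal and overestimates;
5. reports batch statistics: left/right ratios (≈1 for symmetric
   skeletons; the readout for asymmetry phenotypes), intra-limb ratios
   (humerus/radius, femur/tibia), and cross-batch coefficients of
   variation (100·SD/mean).

A capsule-phantom generator with analytic ground truth (true length =
axis + 2·radius, exact by construction) backs every validation claim; see
`vignettes/osteobox-methods.Rmd` for the model, parameter defaults and
design rationale.

## Worked example

Generate a ground-truthed whole-body phantom (12 bones, mirrored
left/right, mild noise), run the full pipeline, and report:

```r
library(osteobox)

ph  <- make_body_phantom(noise_sd_hu = 15, seed = 42)
tab <- measure_bones(ph$volume, ph$landmarks, threshold_hu = 398,
                     specimen = "demo", batch = 1)
tab[, c("side", "bone", "length_mm", "feret_mm")]
#>     side     bone length_mm feret_mm
#> 1   LEFT CLAVICLE     1.589    1.591
#> 2  RIGHT CLAVICLE     1.590    1.592
#> 3   LEFT    FEMUR     3.090    3.093
#> 4  RIGHT    FEMUR     3.090    3.093
#> 5   LEFT  HUMERUS     3.210    3.211
#> ...

export_csv(tab)[1:2]
#> [1] "LEFT CLAVICLE,1.589" "RIGHT CLAVICLE,1.590"

lr_ratio(merge_and_clean(tab))[, c("bone", "lr_ratio")]
#>       bone lr_ratio
#> 1 CLAVICLE   0.9997
#> 2    FEMUR   1.0000
#> 3  HUMERUS   1.0002
#> 4   RADIUS   0.9999
#> 5    TIBIA   1.0000
#> 6     ULNA   1.0001
```

The phantom's true lengths are analytic (clavicle 1.600 mm, femur
3.100 mm, ...), so the measured values above sit within the expected
one-to-two voxel discretisation band (voxels are 20 um; the clean-up
erosion shaves roughly half a voxel per surface), and the left/right
ratios recover the built-in symmetry to < 0.1%. Asymmetry phenotypes are
detected the same way: `make_limb_pair(asymmetry_percent = 10)` yields a
measured ratio within a fraction of a percentage point of 0.9.

A thin command-line front end over the same functions lives in
`inst/cli/osteobox.R`:

```sh
Rscript inst/cli/osteobox.R phantom --output ph --seed 3 --noise 10
Rscript inst/cli/osteobox.R measure --input ph --landmarks ph/landmarks.csv \
        --threshold-hu 398 --specimen S1 --batch 1 --out m1.csv
Rscript inst/cli/osteobox.R report --tables t1.csv,t2.csv --ratios --cv
```

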