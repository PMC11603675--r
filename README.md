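# palatemap

3D palatal bone-thickness cartography for orthodontic mini-implant
(temporary anchorage device, TAD) planning.

Mini-implants are anchored in the anterior palate, where the decisive
questions are geometric: how much bone lies between the oral palatal
surface and the bony floor of the nasal cavity, where is it thickest, how
does the available depth change when the implant is tipped anteriorly by
10-30 degrees, and when does an incisor root sit in the insertion
corridor? `palatemap` answers these questions from CBCT-like volumes, and
ships synthetic phantoms with analytic ground truth so the whole pipeline
is testable without any patient data.

## What it computes

Given an HU volume and a set of anatomical landmarks:

1. **Segmentation** - inclusive HU-window thresholding in the 50-2000 HU
   working range (bone pass at 400 HU, separate teeth pass at 1500 HU),
   26-connected component filtering, marching-tetrahedra iso-surfacing on
   the continuous grey-value field, and bone + teeth mesh merging with
   preserved coordinates and per-face labels.
2. **Anatomical frame** - Y through the anterior/posterior nasal spine
   (anterior+), Z perpendicular to the occlusal plane (superior+),
   X = Y x Z (right+), origin at the ANS-PNS midpoint so the midsagittal
   plane is x = 0.
3. **ROI cartography** - the oral palatal patch is split into six
   paramedian regions (first premolar, second premolar, first molar bands;
   right/left; |x| <= 10 mm). Per ROI: analysis area `AA` (mm^2),
   area-weighted mean oral-to-nasal-floor distance `MD` (mm) and the
   integrated-distance volume `Vol = AA x MD` (mm^3), plus a color-coded
   per-vertex thickness map (PLY).
4. **Angulated probing** - at six points 3 mm paramedian (canine/P1
   contact, P1 mid, P1/P2 contact levels), bone thickness along rays
   tilted 0/10/20/30 degrees anteriorly relative to the palatal surface,
   independent tooth-root conflict flags, and a cylindrical corridor-fit
   check for a given implant diameter and length.
5. **Statistics** - random-intercept linear mixed models (REML, profiled
   variance ratio, Wald-z inference) for cohort tables with repeated
   measurements per palate; descriptive summaries with both printed
   interval conventions (`mean +/- 1.96 sd/sqrt(n)` and
   `mean +/- 1.96 sd`); exact-enumeration Mann-Whitney and Wilcoxon
   signed-rank tests with patient-level averaging against
   pseudoreplication; smoothing-spline age trends.

The synthetic-data module generates slab, spherical-shell and
gradient-wedge oracles, a palatal-vault phantom whose wall thickness runs
from 10 mm anteriorly to 3.5 mm posteriorly (with optional incisor roots
intruding into the anterior corridor and a nerve-canal void), and
simulated patient cohorts drawn from the same mixed model the analysis
fits.

## Worked example

Build the root-bearing vault phantom, run the pipeline, and inspect the
cartography and the angulated probe measurements:

```r
library(palatemap)

ph    <- makeVaultPhantom(roots_on = TRUE, spacing_mm = 0.4)
seg   <- segmentBoneTeeth(ph$volume)
frame <- buildFrame(phantomLandmarks(ph$truth))
bone  <- transformToFrame(seg$bone, frame)
teeth <- transformToFrame(seg$teeth, frame)
oral  <- selectOralPatch(bone)
nasal <- selectNasalPatch(bone)
part  <- partitionRoi(oral, phantomLandmarks(ph$truth))
dmap  <- computeDistanceMap(oral, nasal)
summarizeRoi(oral, part, dmap)
#>     roi     AA    MD    Vol n_valid_vertices coverage
#> 1    1r  66.40 8.497  564.2             2164   0.9865
#> 2    1l  66.19 8.421  557.4             1641   1.0000
#> 3    2r  44.60 7.195  320.9             1479   0.9938
#> 4    2l  44.13 7.121  314.2             1111   1.0000
#> 5    3r  66.76 5.365  358.2             2181   0.9918
#> 6    3l  66.19 5.300  350.8             1641   1.0000
#> 7 total 354.27 6.960 2465.8            10217   0.9951
```

`MD` falls from ~8.5 mm in the first-premolar band to ~5.3 mm at the
first molars -- the phantom's analytic wall profile (8.18 / 5.06 mm at the
band centres) recovered within the half-voxel partial-volume offset, and
`Vol` equals `AA x MD` identically. The probe measurements at point 1r
show the clinically important angulation effect:

```r
pts <- placeProbePoints(oral, phantomLandmarks(ph$truth))
measurePointThickness(pts, c(0, 10, 20, 30), nasal, teeth)
#>  point_id angle_deg thickness_mm root_hit root_depth_mm
#>        1r         0        9.187    FALSE            NA
#>        1r        10        9.761    FALSE            NA
#>        1r        20       10.795     TRUE         5.977
#>        1r        30       11.777     TRUE         4.088
```

Bone thickness to the nasal floor *increases* with anterior tilt, but at
20-30 degrees the ray meets an incisor root at 6.0 / 4.1 mm depth: the
usable depth collapses, which is why low insertion angles are preferred
anteriorly. A corridor check for a 2.2 x 9 mm implant at point 2r:

```r
corridorFit(pts[pts$id == "2r", ], 0, implantSpec(2.2, 9), nasal, teeth)
#> corridor 2r fits: FALSE | limiting: nasal_floor | min thickness: 8.16 mm
```

`runPipeline(defaultRunConfig())` chains all stages and can write a full
report bundle (STL/PLY meshes, CSV tables, model JSON, manifest); a thin
command-line wrapper lives in `inst/scripts/palate.R`.

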