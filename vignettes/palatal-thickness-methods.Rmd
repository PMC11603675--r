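---
title: "Methods: 3D palatal bone-thickness cartography for mini-implant planning"
author: "palatemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D palatal bone-thickness cartography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palatemap)
```

## The clinical question and the measurement model

Orthodontic mini-implants (temporary anchorage devices, TADs) are screwed
into the anterior palate, where bone supply decides whether a 7--11 mm
implant of 2--2.3 mm diameter can be anchored without perforating the nasal
floor or hitting an incisor root. `palatemap` quantifies that bone supply
from CBCT-like volumes in three complementary ways:

1. **ROI cartography.** The oral (palatal) surface is partitioned into six
   paramedian regions of interest -- first premolar, second premolar and
   first molar bands on each side, within 10 mm of the midsagittal suture.
   For each ROI the analysis area $AA$ (mm^2^), the area-weighted mean
   oral-to-nasal-floor distance $MD$ (mm) and the integrated-distance
   volume $\mathrm{Vol} = AA \times MD$ (mm^3^) are reported.
2. **Angulated point probing.** At six insertion-site candidates (3 mm
   paramedian, at the canine/P1 contact, P1 mid and P1/P2 contact levels),
   bone thickness is measured along rays tilted $0^\circ, 10^\circ,
   20^\circ, 30^\circ$ anteriorly "relative to the palatal surface", and
   tooth-root conflicts are flagged separately.
3. **Cohort statistics.** Long-format measurement tables are analysed with
   random-intercept linear mixed models (one intercept per palate, since
   repeated ROI/angle measurements of one patient are dependent),
   validated by exact nonparametric rank tests on patient-averaged data.

Thickness is always the Euclidean distance from the oral bone surface to
the *first* intersection with the bony nasal floor. A root conflict never
truncates the reported thickness; it is recorded as an independent flag
with its own depth, because bone thickness and root risk are clinically
distinct quantities.

## Geometry processing

**Segmentation.** Bone and teeth are segmented with two inclusive HU
windows inside the 50--2000 HU working range: `[400, 2000]` for bone and
`[1500, 2000]` for teeth (enamel/dentin sit above trabecular bone; the
defaults are configurable). Teeth voxels are excluded from the bone pass
so the two surfaces complement each other, mirroring the two-pass
export-and-merge workflow of clinical CAD pipelines. Connected-component
filtering (26-connectivity, secondary components kept above 1000 voxels at
0.3 mm spacing, i.e. 27 mm^3^) stands in for the manual clean-up of
interactive protocols -- an automated substitute, not an equivalent, and
the one step of a human segmentation workflow this package does not try to
reproduce.

**Iso-surfacing.** Surfaces are extracted with marching tetrahedra on the
*continuous* HU field (each grid cell is split into six tetrahedra sharing
a fixed main diagonal, which makes shared cube faces consistent and the
surface watertight wherever it closes). Meshing the grey values rather
than the binary mask places vertices at the sub-voxel interpolated
crossing, which removes the staircase bias that otherwise inflates surface
areas and corrupts normals. Rejected voxels that lie *above* the threshold
(teeth, discarded components) are knocked down to air before meshing;
sub-threshold voxels keep their grey values so the partial-volume gradient
at the bone boundary is preserved. Triangles are wound so normals point
toward the low-HU side (outward). Optional Laplacian smoothing exists
behind a flag (`smooth_iterations`) and is off by default.

**Anatomical frame.** From landmarks: $Y$ = unit vector from the posterior
to the anterior nasal spine (anterior positive); $Z$ = the component of
the occlusal-plane normal orthogonal to $Y$, signed toward the palate
(superior); $X = Y \times Z$ (patient right, checked against the molar
fissures -- a mismatch warns rather than silently flipping, because it
indicates swapped landmark sides). The origin is the ANS--PNS midpoint, so
the midsagittal plane is $x = 0$. Tooth band levels (the probe anchors and
ROI band intervals) are stored as Y-values *in this frame*, which makes
the partition invariant under any rigid motion of the scan.

**Patch selection.** The oral patch is the set of faces whose outward
normal has $n_z < -0.2$; the nasal patch $n_z > +0.2$ (threshold
configurable). Faces occluded along the viewing direction (straight down
for oral, straight up for nasal) are discarded, which removes interior
walls of carved structures such as tooth sockets -- without this filter,
the ceiling of a root cavity would masquerade as palatal surface.

**Distance maps.** Rays are cast from every oral-patch vertex along the
per-vertex anti-normal (the default rule; a frame-vertical rule is
selectable, and the rule used is stamped into the `DistanceMap`). A ray
that does not meet the nasal surface within `max_ray_mm` (default 40 mm,
comfortably above any palatal thickness) marks its vertex invalid. Invalid
vertices are *excluded* from $AA$ rather than zero-filled, and the
retained-area fraction is reported as `coverage` so exclusions are
visible. Vertex weights use the barycentric one-third rule (one third of
each incident labelled triangle's area), which makes $\mathrm{Vol}$ an
exact surface integral of the piecewise-linear distance field and the
identity $\mathrm{Vol} = AA \times MD$ hold algebraically, not
approximately. Whether the published cartography used vertex-uniform or
area-weighted means is not documented in the tooling literature;
area-weighting was chosen because it makes the three quantities mutually
consistent by construction.

**Angulated probing.** The $0^\circ$ direction is the local surface
anti-normal ("relative to the palatal surface"); a selectable alternative
(`zero_reference = "occlusal"`) uses the occlusal-plane perpendicular
instead, matching the other convention in clinical use. Tilts are purely
sagittal: a rotation about the frame X axis toward anterior, as in
clinical practice where the handpiece is tipped forward. The corridor-fit
check sweeps a cylinder of the implant diameter with one axial plus eight
perimeter rays (count configurable) and reports the limiting structure
(`nasal_floor` or `tooth_root`).

## Synthetic phantoms and what they do (not) show

No patient CBCT data are distributed with, or required by, the test suite;
every stage is validated on phantoms with analytic ground truth.

* **Slab**: a uniform plate of thickness $t$; the thickness oracle is $t$
  at $0^\circ$ and $t/\cos\theta$ under tilt.
* **Spherical shell**: concentric spheres; normal-ray thickness is exactly
  the shell thickness everywhere.
* **Gradient wedge**: a linear thickness ramp; its area-weighted mean is
  the ramp midpoint, $(t_\mathrm{from}+t_\mathrm{to})/2 = 6.75$ mm for the
  default 10 to 3.5 mm ramp.
* **Palatal vault**: a partial cylindrical shell whose wall thickness
  interpolates linearly from 10 mm anteriorly to 3.5 mm posteriorly along
  the antero-posterior axis -- the anterior-to-posterior decline that
  published palatal cartography consistently reports (roughly 10 mm around
  the first premolars down to ~3.5 mm at the first molars). Because the
  oral and nasal arcs are concentric, the thickness along the oral-surface
  normal is *exactly* the wall profile at that Y level, which is what
  makes the vault a quantitative oracle rather than just a shape.

With `roots_on`, tooth-HU incisor-root blocks are placed so that probe
rays from the point-1 positions intercept them at $20^\circ$--$30^\circ$
anterior tilt but not at $0^\circ$--$10^\circ$, plus a deeper lateral
tongue reaching into the first-premolar ROI band (the "teeth extend into
the ROI" condition of the cohort models; in the emulated population this
affects 57% of patients). This reproduces, by construction, the
clinically important sign difference: at point 1 the *usable* depth
(minimum of bone thickness and root depth) falls with increasing tilt,
while at points 2/3 on the posterior-sloped vault the thickness rises with
tilt. With `canal_on`, a tubular void through the right posterior shell
emulates the neurovascular canal; the truth field is undefined on its
footprint and the distance map marks the punched region invalid.

Phantom HU fields are rendered with a linear partial-volume ramp about
1.5 voxels wide at every tissue boundary (air -1000, soft tissue 40, bone
1200, teeth 1800 HU). This emulates the partial-volume averaging of real
CT sampling and is what makes grey-value iso-surfacing meaningful; it also
means surfaces sit where the ramp crosses the threshold, displacing each
boundary by a fixed sub-voxel offset. For the vault the oral and nasal
surfaces shift *outward by the same amount*, so wall thickness is
preserved exactly; for the air-backed slab both surfaces move inward,
biasing thickness by about $-0.27$ voxel -- well inside the 2-voxel
acceptance band used throughout.

What the phantoms deliberately do **not** emulate: imaging noise, beam
hardening, scatter, metal artefacts, HU-calibration error of CBCT (grey
values of clinical CBCT do not map exactly to Hounsfield units;
calibration is the user's responsibility), anatomical variability of the
vault shape, and mucosal soft tissue between probe entry and bone. Passing
the suite therefore demonstrates correctness of the geometry and
statistics pipeline, not robustness to clinical image quality.

## The statistical layer

**Descriptives.** Moment-based skewness $g_1 = m_3/m_2^{3/2}$ and excess
kurtosis $g_2 = m_4/m_2^2 - 3$ (bias-adjusted $G_1$/$G_2$ behind a flag,
since either convention is common in clinical reporting). Two interval
conventions are computed and named explicitly, because published
descriptive tables print both under the same "(95% CI)" heading: `ci_mean`
$= \bar x \pm 1.96\, s/\sqrt n$ (the CI of the mean, used in the ROI
tables) and `range_1_96sd` $= \bar x \pm 1.96\, s$ (the population band,
used in the angulated point tables). The constant 1.96 (normal 97.5%
quantile) is used rather than a t quantile, matching the recomputations
that reproduce the printed bounds at $n = 184$.

**Mixed model.** `fitLmm()` fits $y = X\beta + Zb + \varepsilon$ with one
random intercept per palate by REML, profiling the criterion over
$\lambda = \sigma_b^2/\sigma_e^2$ with a 1-D bounded search on
$\log\lambda$; the grouped structure lets $X'V^{-1}X$, $X'V^{-1}y$ and
$\log|V|$ be accumulated per group in closed form, so each fit is a few
milliseconds and the $\lambda \to 0$ boundary is handled without special
cases. Inference is Wald-z with 1.96-based CIs -- a deliberate,
dependency-free choice that differs from the Satterthwaite or
Kenward-Roger degrees of freedom of typical mixed-model software; with
cohort-sized groups ($\geq$ 50 palates) the difference is negligible, and
the test suite cross-checks coefficients and variance components against
both the balanced-design ANOVA closed form and an independent REML
implementation. Separate models for point 1 versus points 2/3 (rather
than one model with interactions) follow the reporting convention for the
opposite-signed angle effects; the generator supports both designs.

**Rank tests.** The Mann-Whitney U and Wilcoxon signed-rank tests use
exact enumeration of the null distribution up to 12 observations
(924 assignments / 4096 sign patterns; midranks make ties exact too) and
the tie- and continuity-corrected normal approximation beyond; the method
used is recorded in the result. Before nonparametric testing, dependent
measurements are averaged per patient (`averageDependent()`) to avoid
pseudoreplication. Age trends are visualised with cubic smoothing splines
under generalized cross-validation.

**Cohort generator.** `sampleCohort()` is the forward simulation of the
model the analysis fits: per-patient covariates (33.7% female, age groups
4--12 / 13--16 / 17--20 with weights 33:42:109, incisor roots in the ROI
for 57%), fixed effects on the mm scale (defaults are plausible
mean-distance coefficients: intercept 9.94, female $-1.12$, teeth $+0.73$,
ROI2 $-4.75$, ROI3 $-6.94$, small age and side terms), a per-patient
random intercept and i.i.d. residual noise. The variance components are
not published for the motivating cohort; $\sigma_b = 1.5$ mm and
$\sigma_e = 1.0$ mm were fixed once as realistic for mean-distance data
with total SD near 2.5 mm and strong within-patient correlation. These
defaults define the simulated study conditions for parameter-recovery and
type-I-error checks; they are not reproduction targets for any published
coefficient table, which would require the unavailable raw data.

## Numerical choices, tie-breaks, degenerate inputs

* Grid values exactly at the iso level are nudged by $10^{-6}$ so edge
  interpolation never produces coincident vertices; zero-area slivers are
  dropped after extraction.
* ROI band intervals are closed below, open above (anterior-closed);
  $x = 0$ exactly is assigned to the right side. The midline strip is
  included by default (`min_paramedian_mm = 0`) and split at $x = 0$,
  since the ROI runs along the median and paramedian suture but is
  reported in left/right sections; the exclusion half-width is exposed for
  users who prefer a suture-free strip.
* Probe-point surface normals are area-weighted averages over faces within
  1.5 mm of the hit point, which suppresses facet-level noise of extracted
  meshes while staying local relative to the 3 mm paramedian offset.
* Ray casting uses a median-split AABB hierarchy with Moller-Trumbore
  intersection ($10^{-9}$ minimum hit distance to ignore the originating
  surface); misses are data (`NA` + invalid flag), not errors.
* Degenerate inputs fail loudly and early: inverted thresholds, coincident
  nasal spines, collinear occlusal landmarks, rank-deficient model
  matrices (naming the aliased terms), out-of-range ages, all-zero
  difference vectors, and phantom spacings too coarse to resolve the
  requested slab (spacing $> t/3$).

## Problem sizes and known limitations

The test suite runs phantoms at 0.3 mm (slab, sphere -- the clinical CBCT
voxel size) and 0.4 mm (vault) spacing, a few hundred thousand voxels and
$\sim 10^5$ triangles each, and the statistical checks use 20 recovery
fits at 200 patients plus 200 null fits at 100 patients; the whole suite
and the acceptance script each complete in well under a minute on a single
core. Sizes were chosen so the geometric discretisation error (bounded by
2 voxels in every acceptance band) is the visible error term.

Known limitations: thickness is purely geometric -- no bone-density (HU)
profile along the insertion path, no cortical/trabecular split, no
biomechanical stability model; angulation is sagittal-only (no lateral
tilt, no posterior/negative angles beyond the configurable range); the
spherical-shell oracle is met to ~$10^{-3}$ mm rather than machine
precision because vertex normals of a faceted icosphere deviate from
radial by $O(h^2)$; and landmark placement itself is an input, not a
detection problem this package solves.
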