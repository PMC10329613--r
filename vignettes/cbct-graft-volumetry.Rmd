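---
title: "Serial CBCT volumetry of grafted alveolar ridges: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial CBCT volumetry of grafted alveolar ridges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbctvol)
```

## The problem

After a severely atrophied alveolar ridge is reconstructed with a milled
bone block, the clinical questions are *how much* new hard tissue the graft
contributed, *how much of it survives* the healing period, and *where* it is
lost. `cbctvol` answers these from three serial cone-beam CT (CBCT) scans —
baseline (T1), an early follow-up after augmentation (T2), and a late
follow-up (T3) — with a fully scripted version of the semi-automatic
workflow used in clinical 3D radiographic evaluations:

1. segment bone vs background on every scan (seeded region growing), and
   teeth separately (seeded watershed within an enamel/dentin gray-value
   gate);
2. exclude the heads of the osteosynthesis screws from the bone label
   (screw bodies remain, as they sit within the grafted volume);
3. rigidly align the follow-up scans to baseline by intensity-based
   registration;
4. subtract the baseline segmentation from each follow-up segmentation by
   logical operators, giving the "new hard tissue" models at T2 and T3;
5. quantify: new volume at T2 and T3 (cm³), the volume-stability ratio
   `100 · vT3 / vT2` (%), the Dice similarity coefficient (DSC) between the
   two new-tissue models, a signed-surface-distance colormap (loss negative
   / red, gain positive / blue), and linear ridge dimensions at implantation
   sites;
6. aggregate a cohort: descriptives (mean ± SD, median, min–max), the
   Wilcoxon matched-pairs signed-rank test of vT2 vs vT3, and Spearman's
   rank correlation between the T3/T2 ratio and the DSC.

Because clinical CBCT series cannot be redistributed, the package ships a
synthetic phantom generator that emulates the whole study — ridge, graft
block, screws, resorption, scanner physics and patient repositioning — with
exact ground truth, so every stage is testable end to end.

## Segmentation

### Competitive seeded region growing

`grow_from_seeds()` partitions the volume into the seeded labels. Each seed
grows its own region through a priority queue keyed by
`|voxel intensity − region reference mean|`, with ties broken by geodesic
step count, then label code, then voxel index; growth is 6-connected and
deterministic, and the result does not depend on the order in which seeds
are listed. Keeping one region per *seed* (rather than per label) matters:
the background label legitimately contains both soft tissue (dark) and
teeth (very bright), and a single pooled mean would represent neither.

By default each region's reference mean is **frozen** to the mean intensity
of a 1 mm ball around its seed — the tissue sample the rater clicked on.
Two regions then meet exactly at the midpoint of their reference
intensities, so the segmented surface is an iso-intensity surface that
reproduces across serial scans of the same anatomy. A `running` mode
(means updated as regions absorb voxels) is available; it adapts to
intensity drift but couples the boundary position to the claiming history,
which we found shifts boundaries between scans of identical anatomy —
poison for subtraction volumetry.

### Half-height boundary refinement and partial-volume unmixing

Quantitative CBCT conventionally places a bone boundary at the *half
maximum height* of the local intensity profile. `refine_boundary()`
implements this as a narrow-band relabeling: a voxel within ~1.6 voxels of
the grown boundary is bone when its intensity exceeds the midpoint of two
local references — Gaussian-weighted means (σ = 0.45 mm) of the label
interior and exterior, taken only from voxels ≥ ~2 voxels away from the
boundary (outside the partial-volume ramp) and, for the interior, below an
intensity cap (the tooth gate's lower bound) so metal and enamel cannot
inflate the bone reference.

`bone_fraction_map()` goes one step further and converts the boundary band
into per-voxel *bone fractions* by linear unmixing,
`(v − m_out) / (m_in − m_out)` clamped to [0, 1]. Binary labels quantize
the surface to the scan's own voxel lattice; two scans of the same anatomy
therefore disagree by up to half a voxel everywhere, and a subtraction
rectifies that jitter into a systematic positive crust. Fraction maps carry
the sub-voxel surface position and make the subtraction insensitive to how
each scan's grid happened to sample the anatomy.

Titanium screws need context: a bright partial-volume halo ring around a
screw is metal + bone when the neighborhood is bone (fully hard, fraction
1) but metal + soft tissue when the graft has resorbed away around it
(only its small metal fraction counts). The halo (within 0.6 mm of
metal-bright voxels) is therefore classified by whichever deep reference
dominates its neighborhood.

### Watershed tooth segmentation

Teeth share a gray-value window; `watershed_from_seeds()` restricts the
volume to that window and priority-floods the gradient-magnitude landscape
(central differences after Gaussian smoothing, σ = 1 voxel by default)
from one seed per tooth, so each tooth receives its own label and
boundaries form on gradient ridges. The pipeline also *excludes* a dilated
tooth zone (2.6 voxels by default) from the bone label at every timepoint:
the enamel partial-volume rim passes through bone-like gray values, and
excluding it consistently keeps tooth rims out of the difference models.

### Global thresholding

`global_threshold()` is the fully automatic comparator — one gray-value
window, optionally within a region of interest. It recognizes no anatomy,
which is exactly why it is useful as an independent cross-check of the
semi-automatic route.

## Registration

`register_rigid()` maximizes normalized cross-correlation (same-modality
serial CBCT; Mattes-style mutual information is available by configuration)
over the 6-parameter rigid group, using a 3-level multiresolution pyramid
(shrink 4/2/1 with matched Gaussian smoothing), Nelder-Mead at each level,
and intensity-centroid initialization. The returned transform maps
baseline physical points into follow-up space and is used directly for
resampling follow-up labels and fraction maps onto the baseline grid
(labels nearest-neighbor; fractions and intensities trilinear). Both
follow-ups are registered to T1 independently, so all comparisons live in a
single frame. A result that fails to improve on the identity alignment is
flagged and never silently substituted.

The pipeline registers intensity volumes with the metric restricted to the
baseline bone label dilated by 2 mm; the label confines the metric to
anatomy that exists at both timepoints while the dilation retains the
bone/soft-tissue edges that actually drive the alignment.

## Subtraction and metrics

All comparisons happen on the T1 grid. The new-tissue model at a follow-up
is `bone(follow-up, resampled) AND NOT bone(T1)`; the binary model (used
for DSC, colormaps, meshes) is the fraction difference thresholded at 0.5,
cleaned by removing 26-connected components below 20 voxels. The reported
*volume* is the sum of the fraction difference over the kept components
plus their ~0.6 mm partial-volume shell. Two details:

- the baseline fraction map is smoothed with a Gaussian of
  σ = √(1/6) voxel before subtraction, matching the smoothing that
  trilinear resampling imparts on the follow-up maps (a trilinear kernel
  with uniformly distributed sub-voxel offsets has variance 1/6 voxel² per
  axis), so the two surface profiles are compared like for like;
- on surfaces present in both scans, fraction differences below 0.2 are
  treated as grid-sampling jitter and zeroed. This is the method's
  resolution limit: genuine tissue layers thinner than ~0.2 voxel deposited
  on an existing surface are not detectable.

`dice_coefficient()` is voxel-set Dice, `2|A∩B| / (|A|+|B|)`, defined as 1
when both sets are empty (the two models agree there is nothing — flagged
in output). `signed_surface_distances()` extracts the reference model's
isosurface (marching tetrahedra at the 0.5 level, closed and consistently
oriented) and interpolates the comparison model's signed Euclidean distance
field at each vertex: negative where tissue receded (rendered red),
positive where it extends beyond the reference (blue).

Linear ridge dimensions follow the half-height-refined bone label: on the
cross-sectional plane through a site's crest reference point, the
horizontal width is the bone-covered chord along the buccolingual axis at
1, 3 and 5 mm below the crest (configurable), and the vertical height is
measured from a reference plane a configurable offset below the crest to
the most coronal bone sample. The exact landmark protocol of clinical
linear measurements varies between studies; this implementation is a
documented, reproducible stand-in with every choice exposed.

The cohort report computes the mean of *per-case* T3/T2 ratios, not the
ratio of mean volumes; the two differ whenever volumes and ratios are
correlated, and only the former matches per-patient stability tables.

## Statistics

`wilcoxon_signed_rank()` drops zero differences (classical convention;
Pratt handling would change only ties-with-zero edge cases), assigns
average ranks to ties, and computes the two-sided p exactly by enumerating
all 2^m sign assignments for m ≤ 15 nonzero pairs; beyond that it uses the
normal approximation with tie correction and continuity correction.
`spearman_rho()` is the Pearson correlation of average ranks with an exact
permutation p for n ≤ 8 and the t approximation otherwise.
`paired_sample_size()` finds the smallest n whose two-sided paired t-test
reaches the target power via the noncentral-t power function; for
dz = 0.55, α = 0.05, power 0.80 it returns 28 (matching
`power.t.test(type = "paired")`). Published sample-size statements derived
from the same inputs sometimes differ — software defaults vary — so the
function documents its own computation rather than reproducing any
particular printed figure.

Normality and variance-homogeneity screening (Shapiro-Wilk, Levene) are
routine checks available in base R and `car`; the package records
distributional summaries and does not reimplement them.

## The phantom generator

`phantom_spec()` describes a synthetic study case on a 128³ grid of
0.25 mm isotropic voxels (32 mm field of view):

- an atrophied ridge: an extruded cross-section with a parabolic taper
  from a 10 mm base to a 3 mm crest over 14 mm height, with a ~1 mm
  cortical shell around a trabecular core — sufficient for testing
  segmentation, registration and volumetry, with no claim of anatomical
  fidelity;
- two teeth (bright cylinders embedded at the crest) so the watershed and
  tooth-exclusion steps are exercised;
- a graft block on the buccal face: footprint 12 × 10 mm, buccal
  protrusion solved by bisection so the voxelized block hits the target
  volume (0.75 cm³ by default, the typical magnitude of clinical graft
  volumetry) within a fraction of a percent;
- two titanium fixation screws through the block into the ridge, each with
  a protruding head — the screw-head-exclusion rule is testable because
  the generator emits the head masks;
- resorption between T2 and T3 (32% by default, matching reported
  resorption of cancellous allograft blocks) as a smooth, direction-biased
  recession-depth field: a block point survives when its interior depth
  exceeds `τ · w(direction) · (1 + ε)`, with bias weights
  buccal 3 / crestal 2 / lingual 0.7 / apical 0.3 (loss concentrated
  buccally/crestally, as observed clinically), ε a smooth random field
  (σ = 1.5 mm, SD 0.35), and τ solved so the removed fraction is exact.
  Screw bodies never resorb. A smooth recession field — rather than
  voxel-wise random erosion — is what tissue remodeling looks like at
  CBCT resolution, and it gives the resorbed surface a physically
  meaningful partial-volume structure;
- scanner physics: per-tissue intensity texture (means 50 / 600 / 700 /
  1200 / 1600 / 3000 for background, trabecular, graft, cortical, enamel,
  titanium; unitless CBCT-like gray values), Gaussian partial-volume blur
  (σ = 0.25 mm), and additive noise (SD 50, about 10% of the bone-to-soft
  contrast);
- patient repositioning: a true rigid misalignment per follow-up (5° / a
  few mm by default), rendered by evaluating the scene's analytic
  predicates and interpolated fields directly in the moved frame — *not*
  by resampling a rendered image, so all three scans share an identical
  point-spread function, exactly as repeated scans of a repositioned
  patient do.

Two voxelization details are deliberate. Axis-aligned planar faces (block
footprint, ridge base and ends) are snapped to voxel *edges*: a plane
through voxel centers makes the voxelized ground-truth volume ambiguous by
half a voxel over the whole face, whereas a plane on voxel edges voxelizes
exactly, so the emitted truth volumes are the continuous-scene volumes.
And the resorption criterion is kept as a continuous field so the moved
frames can evaluate it by interpolation rather than by resampling a binary
mask.

What the phantom does *not* model: beam hardening, scatter and metal
streak artifacts, anatomical detail (sinus, nasal floor, incisive canal),
intensity calibration drift between visits, and patient motion blur.
Passing the phantom suite therefore demonstrates the pipeline's numerical
correctness and its robustness to noise, partial volume and
repositioning — not robustness to reconstruction artifacts, which in
clinical use are handled by the rater's seed placement and edits.

`make_cohort()` draws per-case graft volumes from a lognormal distribution
(meanlog `log(0.75) − 0.456/2`, sdlog 0.675, i.e. mean 0.75 / SD ≈ 0.57
cm³) and resorption fractions from Beta(1.7, 3.6) (mean 0.32, SD ≈ 0.19),
the magnitudes reported for cancellous allograft cohorts; `render = TRUE`
rasterizes every case, while the default emits the ground-truth table for
statistic-level simulation.

## Numerical choices and problem sizes

- Distance transforms are exact Euclidean (Felzenszwalb lower-envelope
  passes) with anisotropic spacing; a large finite sentinel stands in for
  "no site" so envelope arithmetic stays NaN-free.
- Isosurfaces use marching tetrahedra (6 tetrahedra per cube, vertices
  deduplicated per edge), which needs no case table and yields closed,
  consistently oriented meshes; enclosed volume is the divergence-theorem
  sum.
- Label resampling is strictly nearest-neighbor; fraction/intensity
  resampling trilinear. Ties in all priority queues resolve by content
  (value, label, lexicographic index), never by insertion order.
- The registration optimizer is derivative-free (Nelder-Mead) with
  parameter scaling of 0.5° / 0.5 mm per unit step and ~300/200/100
  iteration caps per pyramid level; the identity-alignment metric is the
  fallback reference for the failure flag.
- Default test problem sizes: unit and property tests run on 6³–24³
  analytic grids and a 64³ / 0.5 mm coarse phantom covering the same 32 mm
  scene; the acceptance suite runs the full 128³ / 0.25 mm study scale,
  five noise-free and three noisy cases, with statistic-level cohort
  simulation (200 replicates of 23 cases) rather than 200 rendered
  cohorts.

## Known limitations

- Sub-resolution changes (layers thinner than ~0.2 voxel on existing
  surfaces) are invisible by design of the jitter deadband.
- The phantom's DSC between the T2 and T3 new-tissue models is a property
  of the simulated geometry (~0.8 at default settings); it is not tuned to
  reproduce any particular clinical cohort's mean DSC, which depends on
  real defect morphologies.
- Linear measurements implement a documented stand-in protocol; absolute
  agreement with any specific clinical landmark protocol is not claimed.
- Mesh-based DSC (on surfaces rather than voxel sets) is out of scope;
  voxel-set DSC is the implemented definition.
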