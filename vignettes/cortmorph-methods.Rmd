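---
title: "Quantifying neonatal cortical morphology: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neonatal cortical morphology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cortmorph quantifies the folding of the developing cerebral cortex from 3D
tissue-label volumes: the kind of segmentation produced from T2-weighted MRI
of preterm infants around 30 and 40 weeks postmenstrual age (PMA), with
labels for unmyelinated white matter (UWM), cortical grey matter (CoGM) and
extracerebral CSF. This vignette explains each measurement, the choices
behind it, what the synthetic phantom cohort does and does not emulate, and
the package's known limitations.

## The descriptor set

Eight descriptors are computed per image, whole-brain and for 10 regions
(2 hemispheres, 8 lobes):

* **Tissue volumes** `V_UWM`, `V_CoGM`, `V_CSF` (cm³): label voxel count
  times physical voxel volume, always on the native grid.
* **Inner and outer cortical surface area** `A_inner`, `A_outer` (cm²): the
  UWM–CoGM and CoGM–CSF/background interfaces, estimated from weighted
  voxel faces (below).
* **Median cortical thickness** `T_median` (mm): Laplace-equation streamline
  thickness, summarized by the voxel median.
* **Gyrification index** `GI`: inner cortical area divided by the area of
  the convex hull around the white matter; 1 for a convex brain.
* **Global mean curvature** `C_global`: a normalized summation of local
  mean curvature over both cortical surfaces; 1 for concentric spheres.

All geometry is computed in physical millimetres. Clinical neonatal
acquisitions are strongly anisotropic (e.g. 0.35 × 0.35 × 1.2 mm), so index
arithmetic is never trusted: volumes and the thickness solver work directly
on the anisotropic grid, while the surface-area, hull and curvature stages
require isotropic voxels and by default resample the label map (nearest
neighbour) to the smallest in-plane spacing first. Whether a study should
measure on the native or a resampled grid is not a settled question; the
resampling policy is therefore a documented default, not hard-wired.

## Configuration-weighted surface area

A naive count of boundary voxel faces overestimates the area of any smooth
surface by up to ~50% (the staircase effect). cortmorph assigns each
boundary face a weight determined by the configuration of the surrounding
voxels: the object's occupancy field is smoothed with a small Gaussian
(`sigma = 1.2` voxels), the local surface normal **n** is estimated from
its gradient at the face centre, and a face with axis direction **e**
contributes `h² |n·e|`. Summing these projections is exact for planes of
any orientation and accurate to a fraction of a percent on digitized
spheres at the working resolutions. Two caveats are deliberate:

* sharp 90° creases (cube edges) are locally ambiguous for any estimator
  built on a smooth-surface model and round off, costing ~2% on a 40 mm
  cube — irrelevant for anatomical surfaces, visible in synthetic edge
  cases;
* the unweighted face count remains available
  (`surface_area(..., method = "face_count")`) as a cross-check.

The gyrification index computes its numerator (inner area) and denominator
(hull boundary area) with the *same* estimator so that residual estimator
bias largely cancels in the ratio. The convex hull itself is the exact 3D
hull of the white-matter voxel centres (incremental quickhull), voxelized
on the same grid; "smoothing" of the hull is available as an optional
morphological pre-closing but is off by default, since the exact hull is
the cleaner definition.

## Laplacian streamline thickness

Thickness follows the harmonic-potential construction: solve ∇²ψ = 0 on
the CoGM domain with ψ = 0 on the inner (UWM) boundary and ψ = 1 on the
outer (CSF/background) boundary, then integrate the normalized gradient
from each CoGM voxel forward and backward; the thickness at a voxel is the
total arc length of its streamline. Implementation choices that matter:

* **Dirichlet data live on tissue faces, not neighbour centres.** The
  7-point stencil uses half-length links to boundary faces; without this
  the slab answer is biased a full voxel. A 3 mm slab at 0.25 mm voxels is
  recovered to machine-level accuracy, and at d/6 spacing within 2%.
* **Solver**: red–black successive over-relaxation (ω = 1.9) to a maximum
  residual of 1e-5. The contract is the residual; the iteration scheme is
  internal.
* **Streamlines**: midpoint (RK2) steps of a quarter voxel (halving the
  step again moves the median by < 0.2%), trilinear interpolation, and the
  final segment clipped where it crosses the tissue face. A 30 mm length
  cap (far beyond any plausible cortex) terminates runaway paths, which
  are flagged invalid rather than silently kept.
* **One-voxel cortex**: voxels touching both boundaries cannot carry a
  streamline; they receive the face-to-face distance and are flagged
  `pinned`. At clinical through-plane resolutions this fraction is a
  routine QC number and is reported, not hidden.
* The median (not the mean) summarizes the field because partial sulcal
  CSF visibility locally *overestimates* thickness; the median is robust
  to that tail.

## Mesh-based curvature

`C_global` needs per-vertex mean curvature on both cortical surfaces. The
binary region (UWM for the inner surface, UWM+CoGM for the outer) is
smoothed with a 1-voxel Gaussian, the 0.5 iso-surface extracted by
marching tetrahedra (closed, consistently oriented, no topology
correction — component counts are reported instead), lightly
Laplacian-smoothed under a < 2% volume-drift guard, and mean curvature is
computed with the cotangent Laplace–Beltrami operator and Meyer mixed
Voronoi areas. The global measure is the curvature energy

$$C = \sqrt{\frac{\int_{inner} H^2\,dA + \int_{outer} H^2\,dA}{8\pi}},$$

chosen because it is scale invariant, equals exactly 1 for any pair of
concentric spheres (each contributes 4π), is bounded below by ~1 for
closed surfaces (Willmore), and grows with folding. Since discretization
noise in H inflates a squared integral, the per-vertex H field is smoothed
on the mesh (60 neighbour-averaging sweeps) before squaring; on spheres
this brings C from ~1.3 to within 2–3% of 1. An L1 variant
(`variant = "absolute"`) and a per-surface averaging variant
(`combine = "mean"`) are provided for sensitivity analysis. Note that C is
the most resolution-sensitive descriptor: sub-voxel curvature detail is
genuinely unmeasurable, so C values are comparable only within one
resolution and smoothing setting.

## Regional analysis and increase factors

Regions follow an atlas-style parcellation into frontal, temporal,
parietal and occipital lobes per hemisphere. For phantoms the package
provides a geometric octant parcellation (right hemisphere x > 0; lobes by
the sign pattern of y and z). Regional restriction rules:

* volumes: mask intersection (lobar values sum exactly to the whole);
* areas: each face belongs to the region of its carrying voxel (faces
  partition, so lobar sums match the whole within rounding);
* regional GI: region-restricted inner area over region-restricted hull
  area, hull faces inheriting the region of the nearest UWM voxel (the
  hull is not anatomically partitioned by construction, so this assignment
  rule is a documented interpretation);
* regional C: vertex sums restricted by the region of the nearest brain
  voxel, normalization unchanged (regional values are therefore not
  expected to average to the global one).

Longitudinal change is summarized per subject as the ratio of the 40-week
to the 30-week value, per region and descriptor; cohort tables then
average these per-subject factors (never the ratio of cohort means).

## The phantom generator

The synthetic stage provides folded two-shell brain phantoms with known
ground truth. The white matter is the region under the radial graph

$$\rho(\theta,\varphi) = R_0\,(1 + a\,S_{w,b}(\sin l\theta \sin m\varphi)),$$

where $S_{w,b}$ is a monotone tanh shaping of the separable sinusoid:
`wall_width` (w) sharpens fold walls and `wall_bias` (b) makes gyral
plateaus and sulcal slots unequally wide. With `w = Inf` the surface is the
plain sinusoidal fold. The cortex is the *constant-thickness distance
offset* `0 < dist(UWM) ≤ t_cortex` and the CSF a further distance rind.

Two properties of this construction are the point:

* a radial graph never self-intersects, so amplitudes up to `a < 1` are
  geometrically valid, and every inner-surface quantity has an analytic
  parametric form for quadrature oracles;
* a distance-offset cortex self-merges wherever a sulcal slot is narrower
  than `2 t_cortex`. This reproduces, by construction, the signature of
  partial sulcal-CSF visibility in clinical neonatal images: outer
  cortical area *below* inner area, and median thickness *above* the
  volume-to-area mean. A cohort whose mean CoGM volume, inner area and
  median thickness simultaneously match the reference values (107 cm³,
  964 cm², 1.4 mm — mutually inconsistent for any non-merging uniform
  sheet) is only reachable in this regime.

The voxelizer widens the distance band by 0.2 voxels to cancel the
sub-voxel bias of measuring distance to voxel centres rather than to the
analytic surface; without this, shell volumes are biased low by ~2–3% at
0.5 mm.

**Ground truth.** `oracle_descriptors()` computes V and A by midpoint
quadrature of the parametric integrals (refinement-checked to 1e-3,
refused otherwise), GI from the exact polyhedral hull of a dense surface
sample, and C from the analytic fundamental forms of the inner surface
plus its curvature-clipped outward offset. CoGM/CSF volumes, outer area
and the two-surface nearest-distance thickness oracle come from a
fine-grid voxelization (half the working spacing by default), since
offset-surface merging has no closed form.

**Calibrated profiles.** `phantom_profile("preterm30")` and
`phantom_profile("term40")` are fixed parameter sets emulating the two
imaging timepoints of a longitudinal preterm cohort. They were calibrated
once, by deterministic coordinate searches, so that the descriptors
*measured by this package's pipeline at the nominal 0.7 mm resolution*
match the reference cohort means (40 weeks: inner area 964 cm², GI 2.7,
CoGM volume 107 cm³, median thickness 1.4 mm; 30 weeks: GI 1.4, and a
40/30 UWM-volume ratio of 1.84). Measured folded-surface area at 0.7 mm
sits 2–4% below the parametric oracle — exactly the kind of
resolution-dependence real studies have (the "coastline" effect) — and the
reference values are themselves finite-resolution measurements, so the
calibration targets the measured values; oracle values are reported
alongside and stay within ~4%. Two deliberate departures from a literal
cohort: phantom white-matter volume is smaller than a real brain's
(matching GI, inner area *and* absolute UWM volume simultaneously would
require fold features below voxel size — the hull area pins the envelope),
so only the UWM *ratio* is calibrated; and the oracle global curvature of
the shaped folds is much larger than the measured one because wall-edge
curvature lives at scales the mesh pipeline (deliberately) smooths away.
C is therefore validated through exact sphere cases, scale invariance and
monotonicity, not through cohort means.

**Cohort simulation.** `generate_cohort()` draws per-subject geometry:
a shared subject size factor and per-timepoint size, amplitude and
thickness jitters (lognormal, CVs of 2.5–5%, chosen to reproduce the
reference between-subject dispersions of ~4–12%), abnormality classes with
the reference proportions (27/35/23 of 85 for the CoGM score;
moderate+severe merged), PMA draws (30.7 ± 0.8 and 41.1 ± 0.5 weeks), and
a fissure width increasing with class. Class effects enter the geometry
through interpretable knobs: thickness effects add to `t_cortex`, GI
effects scale the fold amplitude through the calibrated sensitivity
dGI/d log a (global curvature rides on the same knob — it cannot be moved
independently of GI in this family), and area effects scale `R0`. The
default effect profile encodes the reference pattern at term: thickness
*increases* (+0.067 mm for moderate+severe), GI and curvature *decrease*.
Per-subject seeds are split deterministically from the root seed, so any
subject subset regenerates identically.

`simulate_descriptor_cohort()` is the table-level twin: it draws
descriptor values directly (subject random intercept + region offsets +
class effect + residual noise) for statistical validation at full cohort
size, where generating 170 images would be pointless.

What the phantoms do **not** emulate: MR intensities and segmentation
errors; anatomical gyral geometry (folds are a separable harmonic
pattern); hemispheric asymmetry; any real lobar anatomy (octants); and
descriptor correlations beyond those induced by shared geometry. Passing
tests show the *measurement machinery* is accurate and the *statistical
machinery* recovers known effects — not that the generator is a brain.

## Statistics

`fit_lmm()` wraps lme4: REML fits with a per-subject random intercept,
effects reported against fixed reference levels (class `normal`,
hemisphere `L`), Wald-z p-values (the inference convention here; exact
small-sample inference is out of scope), and a logged downgrade to a
fixed-effects `lm` when subjects contribute single observations.
Rank-deficient designs are refused naming the aliased columns. Model
comparison (`select_model_aic()`) refits candidates by maximum likelihood
— REML AICs are not comparable across fixed structures — and breaks ties
toward fewer parameters. `class_effect_table()` reports per-descriptor
class effects at α = 0.05 without multiplicity correction (a Holm option
exists, off by default, matching common practice in this literature);
descriptors with no significant class effect are flagged rather than
dropped. `spearman_assoc()` uses mid-ranks and the t approximation for
two-sided p-values.

## Numerical choices at a glance

| Stage | Parameter | Default | Note |
|---|---|---|---|
| resampling | target spacing | min in-plane | surface stages only |
| area | normal smoothing σ | 1.2 voxels | planes exact; spheres < 1% |
| hull | candidate pruning margin | 4 mm | envelope-band pruning, large maps only |
| Laplace | residual tol / ω | 1e-5 / 1.9 | red–black SOR |
| streamlines | step / cap | h/4 / 30 mm | step-halving changes median < 0.2% |
| mesh | field σ / smoothing | 1.0 voxel / 10 iters | volume drift guard < 2% |
| curvature | H smoothing | 60 sweeps | needed for the H² integral |
| phantom | band widening | 0.2 voxels | distance-to-centre bias |
| stats | α / correction | 0.05 / none | Holm available |

## Problem sizes

The test suite validates on spheres, slabs, shells and small folded
phantoms at 0.5–2 mm spacing, and runs the calibrated cohort comparison
with 3 subjects per timepoint at 0.7 mm (thickness on cropped 0.35 mm
octant grids, where the 4-voxel-thick cortex keeps the median bias at
2–3%; at 0.5 mm full grids it is +7%). The acceptance script uses 5
subjects per timepoint and the full n = 85 table-level cohort for the
statistics stage. These sizes are the package's validation design; all
stages scale to full-resolution clinical volumes.

## Known limitations

* Surface area and GI are resolution-dependent by nature; cross-study
  comparison of absolute values is meaningless without matched resolution
  and estimator (the package reports the estimator's own convergence
  behaviour on spheres instead of pretending otherwise).
* `C_global` is additionally smoothing-dependent and its absolute scale is
  tied to the package's mesh pipeline; use it comparatively.
* The mesh and voxel area estimators agree to ~3% on convex shapes but can
  differ by up to ~10% on coarsely sampled deep folds (mesh smoothing
  shrinks folds); the voxel estimator is the one used for descriptors.
* The Laplace solver flags, but does not repair, CoGM components isolated
  from one boundary; topology errors in the input segmentation propagate
  to flagged-invalid voxels, mirroring the no-topology-correction policy.
* Regional GI and regional C depend on documented assignment rules with no
  canonical definition.
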