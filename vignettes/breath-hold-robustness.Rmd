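---
title: "Breath-hold reproducibility and robust lung SBRT planning: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breath-hold reproducibility and robust lung SBRT planning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bhrobust` simulates how well photon and proton lung SBRT plans hold up when
the tumor does not come back to exactly the same place at every breath-hold.
This vignette explains the model, its parameters and assumptions, and the
design choices made where the methodology was genuinely open. Everything here
is qualitative description of what the code computes; the numbers the package
produces come from running it (see the README's worked example and
`scripts/acceptance.R`).

## The problem

In breath-hold (BH) gated treatment the patient holds inspiration during beam
delivery. The reproduced tumor position varies between holds, both
systematically over a treatment course and randomly per hold. For protons
this interacts with a second error source absent for photons: the CT-derived
stopping-power ratio (SPR) that sets the beam range. The question the package
addresses is how three planning strategies — robust optimization against
patient-setup shifts only (3D-PS), against enlarged shifts that absorb BH
variability (3D-BH), and against multiple deformed BH images (4D-BH) —
compare under a probabilistic treatment simulation, for both modalities, and
what happens when BH variability turns out larger than planned.

## Error model

The `uncertainty_model()` holds all standard deviations, split the standard
way into systematic components $\Sigma$ (drawn once per course) and random
components $\sigma$ (redrawn per fraction or per breath-hold), per axis
(LR/AP/CC, mm): patient setup ($\Sigma_{PS}, \sigma_{PS}$), breath-hold tumor
position set A ($\Sigma_{BH\text{-}A}, \sigma_{BH\text{-}A}$, used for
planning and evaluation) and the larger set B (evaluation only), plus a
scalar SPR uncertainty $\Sigma_{SPR}$ in percent. The defaults are the
literature values that define the study conditions; they are data, not free
parameters.

Isotropic shift magnitudes for planning derive from these as the radius
containing 90% of an isotropic 3D Gaussian whose per-axis SD combines the
relevant maxima in quadrature:
$r = \sqrt{\Sigma^2 + \sigma^2}\,\sqrt{\chi^2_{3,0.90}}$ with
$\sqrt{\chi^2_{3,0.90}} \approx 2.5003$. This reading reproduces all three
published magnitudes exactly (5.7 mm setup, 4.1 mm breath-hold, 7.0 mm
combined), which is why it was adopted. The $\pm4.7\%$ SPR perturbation is a
configured constant of the study conditions: it is not derivable from
$\Sigma_{SPR}=3.8\%$ by any quantile rule we were prepared to guess at
(neither $1.645\sigma$ nor $2.5\sigma$ matches), so it is taken as given and
left configurable.

## Discrete shift sets

Three discrete samplings recur:

* **7-point axis set** (`planning_axis_samples()`): zero plus $\pm r$ along
  each axis — the deformed planning image set of the 4D strategies.
* **15-point set** (`setup_shift_samples()`): zero, the 6 axis points, and
  the 8 body diagonals scaled to norm $r$. The source methodology only states
  "15 positions"; we chose the minimal symmetric superset of the axis
  pattern that reaches 15 (faces + vertices + centre). It is symmetric (mean
  zero) and config-switchable if another 15-point geometry is preferred.
* **105-point evaluation grid** (`evaluation_shift_grid()`): 15 systematic
  positions (at the 90% radius of $\Sigma_{BH}$ alone) crossed with 7 per-BH
  positions (at the 90% radius of $\sigma_{BH}$ alone). Each combined shift
  is weighted by the product of the anisotropic per-axis Gaussian densities
  of its two components, normalized. The anisotropic densities (not the
  maxima) are used so that sets A and B differ exactly where their SDs do
  (mainly CC).

## Phantom

Patient CTs are not available, so `generate_phantom()` builds a synthetic
thorax: elliptical body, 12 mm high-density chest-wall shell (700 HU), two
ellipsoidal lungs (-750 HU), heart, esophagus, aorta and spinal cord at soft
tissue HU, and a spherical CTV (default 25 mm diameter) inside one lung. HU
values are fixed nominal constants; optional seeded Gaussian texture noise is
off by default. The geometry is deliberately smaller than an adult thorax
(lungs about 0.9 L total) to keep grids small; what matters for the science
is the density contrast that makes proton range sensitive to what the beam
traverses, and a mediastinum of serial organs distal to the target. The
default tumor sits well inside the ipsilateral lung (wall gap about 16 mm),
so the lung-wall clamp engages only for the largest set-B shifts; tests
exercise the clamp explicitly with wall-abutting tumors.

`hu_to_spr()` is a generic piecewise-linear monotone calibration anchored at
air (0.001) and water (1.0); it is research plumbing, not a scanner curve.

## Breath-hold deformation

A reproduced breath-hold geometry is modelled as a harmonic (Laplacian)
displacement field: each displacement component solves the discrete Laplace
equation on the ipsilateral lung minus the tumor, with Dirichlet values equal
to the rigid tumor shift on tumor voxels and zero on and outside the lung
boundary. The tumor moves rigidly, the lung tissue in between deforms
smoothly, everything outside the lung (ribs, mediastinum) stays static —
matching the intent that 3D-BH plans treat tumor and surroundings as moving
together while 4D images move the tumor relative to static surroundings.
Shifts are first clamped to the lung wall (direction preserved, scaled so the
shifted tumor keeps one voxel of clearance) to prevent impossible anatomy.

Numerics: 7-point stencil with per-axis $1/h^2$ weights; one sparse Cholesky
factorization per phantom (the domain does not depend on the shift) reused
for every shift and component; residual tolerance 1e-3 mm (a direct solve
leaves ~1e-12). Out-of-array faces are zero-flux, which the lung never
touches in practice and which gives the exact linear solution in slab
geometry used as a test oracle. Hard zero Dirichlet at the wall was chosen
over a smoothly damped variant; the field is linear in the shift, which the
tests verify.

The inverse displacement (needed to accumulate dose computed on a deformed
geometry back onto the reference) is obtained by fixed-point iteration
(default 20 iterations) restricted to the dilated domain bounding box, with
the composition residual measured and required below a quarter voxel RMS.
Warping is pull-back resampling: linear for HU/SPR/dose, nearest for masks.

## Dose engines

The clinical TPS engines are deliberately replaced by analytic models — the
robustness questions need the right *sensitivity structure*, not clinical
dosimetric accuracy, and this substitution is the package's declared model
substitution:

* **Photon**: depth dose = build-up times exponential attenuation of
  water-equivalent depth (build-up constant 15 mm, attenuation 0.45%/mm),
  lateral profile = error-function penumbra ($\sigma$ = 4 mm) of a
  rectangular aperture covering the CTV projection plus 8 mm.
* **Proton**: per spot, an analytic Bragg curve (entrance plateau 0.35 of
  peak, proximal width 8 mm, distal fall-off $\sigma$ = 3 mm) in
  water-equivalent path length (WEPL), times a lateral Gaussian
  ($\sigma$ = 5 mm); energy layers spaced 5 mm in WEPL covering the CTV depth
  extent plus a 4 mm range margin; spots on a lateral grid covering the CTV
  projection plus 5 mm; constant RBE 1.1 applied exactly once. An SPR
  perturbation of $\delta\%$ scales WEPL by exactly $1+\delta/100$, so
  photon dose is invariant to it and proton range strictly decreases in it.

WEPL is computed by resampling the SPR volume onto a beam-aligned grid,
cumulative-summing along depth, and resampling back. Setup shifts are applied
in machine coordinates: the beam's lateral coordinates shift by the lateral
projection of the shift while surface-referenced depth is unchanged — the
physically correct first-order behaviour (a patient shifted along the beam
axis keeps the same depth dose below their own surface). Consequently a
lateral setup shift translates dose exactly in a uniform tank, and an axial
one leaves it invariant.

For deformed breath-hold images, proton WEPL is recomputed on the warped SPR
volume (range response to the moved tumor is the phenomenon under study),
while photon attenuation uses the reference image (a static-cloud
approximation: lung-confined deformations change photon attenuation little;
deformation still enters photon dose fully through the accumulation mapping).
Dose on a deformed image is evaluated at the deformed positions of the
reference voxels, which is equivalent to computing on the deformed geometry
and resampling through the inverse field, and keeps every scenario dose a
cheap point-wise evaluation.

Beam angles default to arrangements for a right-sided peripheral tumor
(mirrored for left): six photon entries spread over the ipsilateral
hemithorax, and three near-sagittal anterior proton entries. The proton
choice is the organ-sparing-by-angle principle: spots at the tumor rim whose
rays miss the tumor overshoot far through low-density lung, so the overshoot
corridors are aimed at posterior lung and chest wall, not the mediastinum.
Organs of interest are *not* optimization objectives; their doses are only
reported.

## Robust optimization and normalization

Each strategy expands into its scenario set (planning image x 15 setup
positions x SPR members: 15/45/105/315 scenarios). Nonnegative beam/spot
weights minimize a log-sum-exp-smoothed worst case over scenarios of a
composite objective: (i) a penalty when the scenario's CTV soft-D50% falls
below the 54 Gy prescription, with a differentiable soft quantile (implicit
sigmoid counting, sharpness 2/Gy) and implicit-function gradients; (ii) CTV
uniformity terms (per-voxel underdose below 97% of prescription, hot spots
above 70 Gy); (iii) a quadratic penalty on dose outside the CTV above a
distance-based fall-off envelope (exponential with 15 mm length scale); and
(iv) a chest-wall max-dose penalty above 30 Gy. Objective weights were fixed
once on the default phantom and are configuration. L-BFGS-B with analytic
gradients does the minimizing; per-scenario dose-influence matrices over a
reduced voxel set (all CTV voxels, a sampled 30 mm fall-off shell, sampled
chest-wall voxels) make each iteration a handful of matrix-vector products.

After optimization, `robust_evaluate()` recomputes the exact
(interpolated-quantile) CTV D50% for every robust scenario and
`normalize_plan()` scales all weights so the worst scenario equals 54 Gy —
dose is linear in the weights, so the guarantee is exact up to
interpolation. Every plan therefore meets the robust prescription by
construction, which is what makes the subsequent probabilistic comparison
fair.

## Probabilistic evaluation

A simulated treatment draws: systematic SPR perturbation (from the discrete
set, weighted by the $N(0,\Sigma_{SPR})$ density; photons fixed at 0),
systematic patient-setup and BH shifts; then per fraction a random setup
shift, and per breath-hold delivery unit a random BH shift. The breath-hold
delivery unit is one beam (photon) or sub-beam (proton, after the
more-than-ten-energy-layers split) per fraction — the split exists precisely
so a sub-beam fits in one hold. Three fractions.

Continuous draws are mapped to the discrete scenario grids by nearest
neighbour in Mahalanobis distance (per-axis SDs of the generating Gaussian;
ties to the lowest id): combined systematic+per-BH shift to the 105-image
grid via its two factors, combined setup shift to the 15-point setup grid.
The mapped unit dose comes from a lazily filled cache keyed by (unit, image,
setup, SPR); doses accumulate over fractions and units on the reference
geometry. DVH metrics per treatment: CTV D50%/D2%/D98%/D0% and
HI = (D2% - D98%)/D50%; lung V5Gy/V20Gy (absolute cm^3); heart D0%/Dmean;
esophagus, aorta, spinal cord D0%. Dx% uses the interpolated-quantile
convention in which 100 voxels of 1..100 Gy give D50% = 50.5 and D2% = 98.5;
D0% is the voxel-wise maximum.

Summaries per metric: Avg, SD, Med, IQR, min, max and p90% — the 10th
percentile for CTV dose metrics (dose reached with 90% probability) and the
90th percentile for HI and all organ metrics (value not exceeded with 90%
probability). Evaluations of sets A and B use common random numbers (the
same seed pairs the underlying draws), which sharpens the A-vs-B contrast at
a given sample count.

## Problem sizes and what the tests show

The study-scale run is 10,000 treatments per plan per set; the package's test
suite and examples run the same pipeline at reduced size as its own choice of
problem scale: a 5 mm grid (40 x 32 x 34 voxels), 8 mm energy-layer and spot
spacing, and 200 treatments per plan per set; the deformation suite runs on
the default 3 mm phantom. Scenario counts, image-set sizes and all
combinatorics are always at full scale. The bookkeeping of the full study
(14 phantoms x 6 plans x 2 sets x 10,000 = 1,680,000 treatments) is checked
via the experiment driver's dry-run mode.

Passing tests show that the machinery reproduces the published geometry
exactly (radii, counts, normalization guarantee) and behaves qualitatively
like the study on a synthetic thorax (coverage ordering of strategies,
direction of the A-to-B change, proton sparing of distal organs). They do
not show clinical dosimetric accuracy: the phantom is not a patient, the
engines are analytic, and organ metrics depend on the chosen beam angles.

## Known limitations

No deformable registration of real images; no intra-breath-hold residual
motion; no rotational setup errors; no variable RBE, nuclear halo or
Monte-Carlo transport; photon apertures are rectangular field openings
without MLC sequencing; the static-cloud photon attenuation approximation
above; heart and lung volumes are phantom-sized, so absolute organ metrics
are not comparable to patient values.
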