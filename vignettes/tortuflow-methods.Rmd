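---
title: "Methods: arterial tortuosity, cerebral blood flow and WMH burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arterial tortuosity, cerebral blood flow and WMH burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tortuflow)
```

## The problem

Elongation and kinking of the extracranial brain-feeding arteries — the
internal carotids (ICA) and vertebrals (VA) — are common in aging and are
suspected contributors to chronic hypoperfusion and white-matter
hyperintensity (WMH) burden. Studying that link quantitatively requires a
chain of image-derived measurements: vessel segmentation and centerline
geometry from TOF-MRA, per-artery flow from phase-contrast MRI, tissue
perfusion from pcASL, lesion classification from FLAIR-derived masks, and
a cohort statistics layer. `tortuflow` implements that chain as a tested
package, with synthetic phantoms (each carrying its analytic ground
truth) in place of the non-deposited MRI data.

## Vessel geometry

**Segmentation.** Arterial voxels are selected by an intensity threshold;
foreground voxels are connected when their faces or edges are adjacent,
i.e. 18-connectivity in 3D (corner-only contact does not connect). The
artery of interest is picked by a seed point (`select_component()`),
mirroring the manual ROI step of clinical workflows.

**Centerline.** The centerline is the minimal-time geodesic of an Eikonal
front. The speed map is a medialness prior: the interior Euclidean
distance transform of the mask, normalized to a maximum of 1 and raised
to a power (default 2), so the front runs fastest along the vessel axis.
The arrival-time field is computed by fast marching with multiple stencil
frames — the axis-aligned frame plus three face-diagonal frames — taking
the minimum over frames; this removes the large diagonal-direction error
of axis-only schemes. Second-order one-sided differences are used on the
axis frame only: on the rotated frames the second-order extrapolation can
undershoot on curved fronts, and because a fast-marching value can only
ever decrease during updates, that bias would contaminate the whole
field (we observed −13% before restricting it). A ball of radius 4
voxels around the source is initialized with the exact local solution
and frozen; the initialization ray-tests against the mask so it cannot
tunnel through walls. Measured accuracy against the analytic distance
field on an open 64³ box: max relative error 1.1%, well inside the 2%
criterion; against a 26-neighbour Dijkstra oracle the arrival field never
exceeds the graph distance and under-runs it by at most the chordal gap.
A note on that gap: the worst-case overestimate of a 26-neighbour graph
metric over the Euclidean one in 3D is `(sqrt(3)+1)/sqrt(6) − 1 ≈ 11.5%`
(along (1,1,2)-type directions), not the 7% sometimes quoted from the 2D
case; the tests bound at 11.5%.

The far endpoint is chosen as the most medial voxel within a late-arrival
band (raw argmax-T tends to land in slow near-wall corners of the end
caps). Backtracking is gradient descent on the arrival field with
trilinear interpolation, step 0.4 × the smallest spacing, with a
steepest-discrete-neighbour fallback on plateaus. The raw path carries
sub-voxel jitter that inflates arc length, so it is smoothed with a
Gaussian of σ = half a voxel before resampling; heavier smoothing starts
shrinking genuine curvature (on a helix of 7 mm curvature radius,
σ = 1 voxel already shortens the path by ~2%).

**Turn counting.** The inflection count is automated (the source workflow
used visual inspection): after Gaussian smoothing of the coordinates
(σ = 4 × the resampling step), the discrete Frenet normal is tracked and
a turn is a reversal (negative dot product) of consecutive unit normals.
Two guards make this robust on voxelized data:

* orientation is only trusted where curvature exceeds both an absolute
  floor (`kappa_min = 1e-3` mm⁻¹) and 25% of the curve's 95th-percentile
  curvature — near-straight stretches and residual rasterization wiggle
  carry no orientation;
* orientation lobes shorter than 5 mm of arc are treated as noise and
  removed parity-consistently: an interior short lobe annihilates its
  flip/flip-back pair, a short edge lobe drops its single flip. This
  collapses the flip–flip–flip chatter that otherwise appears where a
  true inflection passes through near-zero curvature.

The first and last 4 mm are ignored (end tangents are unreliable).
Consequence: genuine turns closer than 5 mm apart would be merged — an
accepted limitation at clinical vessel scales, where inter-turn distances
are tens of millimetres. On the acceptance grid (sinusoids of 1–4
periods, amplitudes 5 and 10 mm, noise 0 and 5%), turn counts are exact
in 16/16 cases and the worst ICM error is 4.9%.

**Metrics.** `ICM = turns × L_path/L_chord` (a straight vessel scores 0);
the classical `(turns + 1) × ratio` convention is available via
`convention = "bullitt_plus_one"` because reported magnitudes in the
literature do not disambiguate the two. The subject-level index weights
the territories by their share of intracranial supply:
`ICM_index = 0.8 · ICA_ICM + 0.2 · VA_ICM`, with left/right averaged
per territory first. The ICA angle is the angle between mean tangents of
the CCA and ICA over the first 10 mm from the bifurcation; the window is
a package default (no standard definition exists) and is exposed in the
configuration.

## Hemodynamics

**Phase contrast.** Phase maps to velocity linearly, `v = VENC · φ/π`
(default VENC 60 cm/s, the neck-vessel protocol value); aliased phase is
refused rather than unwrapped. The lumen mask is magnitude ≥ 5× the
background noise SD (noise estimated from vessel-free corners by
default), optionally intersected with a user ROI. Flow is the signed sum
of velocities over the mask times pixel area (cm/s → ml/min via the
factor 10 × 60/1000); reverse-flow pixels therefore subtract, a
convention choice the source material leaves open. Normalized global CBF
divides the four-artery total by the parenchymal mass approximated as
1.06 g/ml × (GM + WM volume), × 100 → ml/100 g/min.

**pcASL.** The consensus single-delay equation with defaults
λ = 0.9 ml/g, α = 0.85, τ = 1800 ms, PLD = 2000 ms, T1b = 1650 ms; times
are converted to seconds inside the formula so the 6000 prefactor yields
ml/100 g/min. ΔM defaults to control − label (the consensus positive
perfusion signal) although the narrative of some pipelines writes
label − control; a `sign` flag flips it. The ASL phantom inverts the
equation exactly, so generate-then-quantify is an identity up to
floating point (measured ≤ 1e−14 relative). Voxels with M0 ≤ 0 are
undefined and excluded from the parenchymal mean.

## Lesions

Lesion masks are ingested (the upstream deep-learning segmenter is out of
scope; a probability map is accepted and cut at 0.5). Components are
18-connected with scan-order-deterministic ids. The distance of each
component to the ventricle is the minimum, over its voxels, of the
Euclidean distance transform of the ventricle mask (0 inside, anisotropic
spacing honored). Classification is per component: deep white matter iff
min distance ≥ 13 mm (the boundary is inclusive to DWM — "13 mm or
further"), because lesions, not voxels, are what gets labeled; a
per-voxel variant exists by flag. Volumes are voxel counts × voxel
volume, and PVWM + DWM always equals the total exactly.

The synthetic lesion scene models the ventricle as a slab so surface
distance has a closed form; offsets are realized exactly when they are
multiples of the z spacing (the boundary test uses 0.1 mm slices so 12.9
vs 13.0 mm is decidable), otherwise to the nearest half voxel.

## Cohort statistics

Normality is gated by a Lilliefors-corrected one-sample KS test (the
classical KS null is invalid with estimated mean/SD). The p-value comes
from a seeded Monte-Carlo null of 1000 simulations in an isolated RNG
stream — exact at any sample size up to simulation noise, deterministic,
and free of transcribed approximation polynomials. Group comparisons use
Welch's t when both groups pass the gate (pooled variance by flag; the
choice is not specified in the source setting), else Mann-Whitney U;
always two-sided, α = 0.05. The 2×2 chi-square is Pearson without
continuity correction — on the published sex-by-severity counts
(17F/22M vs 25F/11M) this gives 5.0786 vs the printed 5.09 (p = 0.024),
a rounding-level difference the data cannot resolve further.
Benjamini–Hochberg adjustment is applied within each analysis block
(group-comparison table, correlation table). Partial correlation
correlates least-squares residuals after projection on [1, covariates],
with `n − k − 2` degrees of freedom. The WMH regression is OLS with the
fixed seven-predictor design on complete cases (missingness is listwise
per analysis and `n_used` is always reported; nothing is imputed);
standardized coefficients z-score the continuous variables, leaving the
sex indicator at 0/1.

## The synthetic cohort

`gen_cohort()` draws demographics at the scales of an elderly WMH cohort
(age 73.1 ± 5.5 y, 42/75 female, SBP 131.1 ± 16.4, DBP 70.4 ± 11.8,
BMI 25.6 ± 4.5; BP missing for 10/75 of subjects) and plants the
dependence structure of interest: a severity group shift of 2.25 on the
ICM index, a partial ICM-index/CBF correlation of −0.35 given age and
sex, and lesion volume linear in ICM index (slope 1.2 cm³ per unit) and
age (0.4 cm³/y) with 5 cm³ residual SD. Two deliberate modeling choices:
the CBF residual is mixed against the *empirically residualized* ICM
(so the planted partial correlation is what a large-sample estimate
converges to, regardless of the group/sex/age entanglement), and lesion
volume is *not* floored at zero — truncation would bias least-squares
recovery of the planted slope, and the regression coverage test depends
on exact linearity. Simulated lesion volumes can therefore be negative;
the generator documents this as a linear-phantom property, not a claim
about anatomy.

## What a green test establishes — and what it does not

The phantoms emulate geometry and signal arithmetic, not MR physics:
additive Gaussian noise (no Rician floor), hard-edged tubes without
partial volume or flow-related enhancement, no cardiac pulsation, a
single vessel per volume, a slab ventricle. Recovery-of-truth results
(turn counts exact, ICM within 5%, flow within 3% at protocol
resolution) certify the *algorithms* on resolvable, well-posed inputs;
they do not certify performance on clinical TOF-MRA with touching
vessels, coiling, or ECA/ICA ambiguity — failure modes the per-subject
runner surfaces as exclusions rather than solving.

One criterion deserves explicit honesty: the scan–rescan harness (CoV of
ICM over 10 noise realizations at SNR 20) evaluates to ~0% against its
≤ 5% bound. With hard-edged tubes, the half-intensity threshold sits
about ten noise SDs from both tissue classes, so every realization
yields the identical mask and centerline. The bound holds, but
trivially; reproducing a realistic 3% scan–rescan CoV would require
partial-volume and repositioning models that are stated non-goals.

## Numerical choices at a glance

| Parameter | Default | Why |
|---|---|---|
| segmentation threshold | half foreground intensity | phantom mid-class split; absolute threshold exposed |
| connectivity | 18 | faces-or-edges adjacency, the stated rule |
| medialness power | 2 | standard axis-pull; exponent exposed |
| FMM init ball | 4 voxels, exact, frozen | removes source singularity (1.1% max error) |
| backtrack step | 0.4 × min spacing | sub-voxel, stable descent |
| path smoothing σ | 0.5 voxel | jitter removal without curvature shrink |
| turn smoothing σ | 4 × resample step | kills rasterization wiggle |
| κ floor / relative | 1e-3 mm⁻¹ / 25% of q95 | orientation confidence |
| lobe persistence | 5 mm | parity-aware noise annihilation |
| ICA angle window | 10 mm | no standard exists; exposed |
| VENC | 60 cm/s | protocol value |
| ASL params | 0.9 / 0.85 / 1800 / 2000 / 1650 | consensus single-delay set |
| PV/DWM threshold | 13 mm, inclusive DWM | the stated rule |
| α, tests | 0.05, two-sided | stated significance policy |
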