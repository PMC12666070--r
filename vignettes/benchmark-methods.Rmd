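---
title: "Complete-to-partial liver registration: generator, solvers and metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complete-to-partial liver registration: generator, solvers and metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liverbench)
```

## The problem

In laparoscopic augmented reality a complete organ surface `X` (M points,
segmented from a preoperative CT) must be aligned to a partial surface `Y`
(N points, N ≪ M, reconstructed from intraoperative stereo video). Only a
patch `X_visible ⊂ X` of the organ is exposed to the camera, the tissue has
deformed between imaging and surgery, and the reconstruction is noisy. The
rigid complete-to-partial registration problem seeks `R ∈ SO(3)`, `t ∈ R³`
with `R X_visible + t ≈ Y`; the rigid estimate is the standard
initialization for later non-rigid refinement. `liverbench` builds a fully
annotated synthetic benchmark for this problem and implements the classical
solvers and evaluation protocol used to study it.

## The synthetic pair generator

Each benchmark pair is produced by a deterministic, per-seed pipeline:

1. **Phantom.** `make_liver_phantom()` builds a watertight two-lobed mesh
   (two jittered ellipsoids blended by a smooth implicit union, extracted by
   radial ray-casting onto a subdivided icosahedron; 2562 vertices, 5120
   faces, genus 0 by construction) scaled to 200 mm width — the size of an
   adult liver. The phantom is a license-clean stand-in for patient liver
   meshes; it reproduces the gross two-lobed geometry but not fine
   anatomical detail (ridges, impressions, vessels), so descriptor-based
   results on real anatomy may differ.
2. **Surface sampling.** 3500 area-weighted samples with recorded
   barycentric coordinates.
3. **Deformation.** One lobe (random left/right) is displaced by a vector
   drawn uniformly in ±25 mm on x and z (y = 0) through as-rigid-as-possible
   (ARAP) deformation: cotangent-weighted local–global iterations, anchors
   fixed on the opposite lobe, 10 iterations. The same barycentric
   coordinates are carried onto the deformed mesh, so source↔deformed
   correspondence is index-exact. This emulates the smooth, lobe-scale
   deformation produced by pneumoperitoneum and patient positioning — not
   the large, local instrument-induced deformations seen in porcine
   stress-test data.
4. **Visibility crop.** Normals are estimated (20-NN PCA, oriented away
   from the centroid), a virtual endoscope is drawn in spherical
   coordinates (polar 15–75°, azimuth 0–360°, radius 2.5× the bounding
   sphere), and points whose normal is within 80° of the direction to the
   camera are visibility candidates. Exactly `round(crop_ratio × 3500)`
   points are kept as one contiguous patch grown by nearest-neighbour
   accretion from the candidate closest to the camera. At the default 15%
   crop this yields 525 target points.
5. **Landmarks.** TRE landmarks (default 20) are chosen by farthest point
   sampling from the *cropped-out* region, so they can never leak into the
   registration inputs.
6. **Normalization.** Source and deformed clouds are mapped to `[-1, 1]`
   with the *source* cloud's isotropic map (centre of the bounding box,
   scale = half the largest extent). A single isotropic scale is used, not
   per-axis min-max: per-axis scaling would destroy rigidity and the rigid
   ground truth with it. The map (~100 mm per unit) converts all
   mm-specified magnitudes both ways.
7. **Rigid perturbation.** Axis uniform on the sphere, angle uniform in
   [0°, 45°], translation components uniform in ±50 mm (converted to
   normalized units), applied about the target centroid so the translation
   bound is meaningful.
8. **Noise.** Element-wise Gaussian noise, σ = 0.01 normalized units
   (≈1 mm), on the target only.

Stage order (deform → crop → normalize → perturb → noise) keeps every
mm-specified magnitude in mm and applies the noise σ on the normalized
scale its value refers to. Every stage draws from its own seed stream
derived from the per-pair seed by a stable string hash, so regeneration is
bit-exact and a manifest (per-pair seed = hash of master seed, source id,
target index) enumerates a dataset without generating any geometry.

Choices the protocol leaves open, fixed here once: camera angle ranges
(15–75° polar — an oblique laparoscopic viewpoint band), patch growth by
contiguous accretion (a single endoscopic view rather than a dispersed
thinning of the visible hemisphere), 20 landmarks, ARAP handle margin 0.3
(handles/anchors beyond 30% of the half-extent from the lobe split plane),
10 local–global iterations, negative cotangent weights clamped at zero so
the global solve stays positive definite and the energy non-increasing.

## Solvers

* **ICP** — identity initialization, target→source nearest-neighbour
  pairing (the sparse partial side drives the pairing, avoiding many-to-one
  collapse from the dense side), closed-form SVD update, stop on residual
  change < 0.001 (read as *change*, not absolute residual) or 30 iterations.
* **Rigid CPD** — EM over a Gaussian mixture with the source points as
  centroids, uniform outlier weight 0.1 (unstated in the protocol;
  configurable), closed-form rigid M-step without scale, variance updated
  in closed form, stop on likelihood change < 0.001 or 50 iterations. The
  classic all-pairs initial variance is the default; `sigma2_init` exposes
  a local alternative (see "Convergence in the complete-to-partial
  regime").
* **GMMReg** — both clouds as equal-weight isotropic mixtures (components =
  target size; the source is farthest-point subsampled to match), rigid
  parameters minimizing the closed-form L2 distance between mixtures by
  BFGS with analytic gradients, bandwidth annealed 0.5 → 0.1 of the target
  diameter (schedule unstated in the protocol; configurable).
* **FPFH + RANSAC** — 33-bin fast point-feature histograms at every point,
  mutual-nearest-neighbour descriptor matches, 3-point Kabsch hypotheses,
  inlier threshold `max_correspondence_distance = 0.05`, best-inlier-count
  model (ties by residual), optional ICP polish. This non-learned front end
  exercises the same correspondences→RANSAC→pose path that learned
  matchers use, so external (trained) matchers can be compared through the
  same machinery.
* **Weighted Kabsch–Umeyama** — closed-form weighted least-squares pose
  from correspondences, determinant-corrected, no scale.

The overlap head and training losses of overlap-guided correspondence
registration are provided as pure operations on arbitrary feature matrices:
per-point scores for the complete cloud are `sigmoid(C w₁ + b₁)`, while
every partial-cloud score is fixed at exactly 1 — in complete-to-partial
registration the partial cloud is contained in the complete one by
definition, so predicting its overlap could only inject estimator error.
The backbone that would produce conditioned features is deliberately out of
scope (GPU-scale training); an adapter interface lets externally trained
models plug into the benchmark instead.

## Metrics

`MAE(R)` is the mean absolute difference of the three z-y-x Euler angles
(wrapped to ±180°), the convention of the partial-to-partial registration
literature; the geodesic angle is reported alongside for transparency.
`MAE(t)` is the mean absolute translation component difference, converted
to mm. `TRE` is the mean landmark distance after applying the predicted
transform, in mm; evaluated at the stored ground truth it isolates the
residual non-rigid component (it equals the ARAP-induced landmark
displacement exactly, and 0 for undeformed pairs) — rigid methods cannot go
below this floor. Correspondence precision/recall counts a predicted pair
correct only when it hits the exact ground-truth index. Tables aggregate
mean ± sample (n−1) standard deviation per method × crop ratio, with a
ground-truth row produced by evaluating the stored transform as a
prediction.

## Convergence in the complete-to-partial regime

The classical solvers are local. Probing them on undeformed, noise-free
pairs shows a structural failure mode specific to complete-to-partial
overlap: any stage that matches *global mass* — CPD's initial all-pairs
variance, GMMReg's coarse annealing stage — drags the centre of mass of
the whole organ onto the small visible patch before local structure can
engage, and the subsequent refinement then polishes the wrong pose. For
CPD this is curable: initializing the variance at a neighbourhood scale
(`(0.1 × target diameter)²`) keeps the E-step local and preserves the
identity-initialized basin. For GMMReg it is not: the L2 cross-correlation
between a full-organ mixture and a patch mixture has its strongest
attractor at mass superposition even for perturbations as small as 2°, so
the method mis-registers from identity regardless of bandwidth schedule —
consistent with its published behaviour on this task. Point-to-point ICP
sits in between: it recovers exactly when the patch locks onto its true
location, but on the smooth phantom surface it falls into tangential-slide
local minima a few degrees away in roughly a third of 10° trials.

The parameter-recovery suite therefore uses undeformed, noise-free pairs
at 15% crop with rigid perturbations up to 10° / 10 mm (the
small-perturbation regime in which local solvers are meant to operate),
runs ICP and CPD with convergence-tightened settings (threshold 1e-6, up
to 100 iterations; CPD with the local variance initialization), and treats
recovery as rotation error ≤ 1° and translation error ≤ 1 mm. Under these
conditions the correspondence-based routes (FPFH+RANSAC, weighted Kabsch
on ground-truth correspondences) recover essentially always and CPD almost
always; ICP and GMMReg do not reach high recovery rates, for the
structural reasons above, and the suite reports that honestly rather than
relaxing the check.

## Problem sizes and numerical choices

Test and acceptance runs use the full 3500-point protocol for single-pair
contracts and for the recovery and trend suites (20 pairs per condition),
and reduced clouds (400–800 points) for round-trip and orchestration
checks; sampler contracts use 10⁴ draws and the noise contract 10⁶
coordinates. Degenerate inputs are handled explicitly: collinear
correspondence support raises an error in the Kabsch solve; an
all-back-facing camera draw raises a visibility error and the generator
retries with a re-derived camera seed (up to 10 attempts); CPD variance
collapse below 1e-12 returns the converged result with a flag; FPS ties
break to the lowest index so subsets are reproducible.

## Known limitations

The phantom is smooth and feature-poor compared to patient livers, which
makes descriptor matching slightly harder and tangential ICP slides
slightly easier than on real anatomy. The deformation model is a single
lobe-scale ARAP displacement; it does not emulate instrument contact,
breathing motion or topology changes. Only the benchmark's file interfaces
(pair archives, manifests, transform JSON) are provided for externally
produced cloud pairs; no real dataset ships with the package.
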