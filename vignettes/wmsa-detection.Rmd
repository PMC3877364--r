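---
title: "Atlas-guided WMSA detection: model, calibration world, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-guided WMSA detection: model, calibration world, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neowmsa)
```

## The problem

Very preterm infants scanned around term-equivalent age frequently show
diffuse T2 hyperintensity of the cerebral white matter (WMSA / DEHSI).
Quantifying it is hard for two reasons: its intensity distribution overlaps
that of CSF on T2-weighted images without fluid attenuation, and visual
grading is unreliable.  The package's answer is to segment the brain with
spatial priors from an age-specific probabilistic atlas, so that
ventricular and peripheral CSF is claimed by the CSF class wherever the
atlas expects CSF, and then to threshold only the voxels the segmentation
considers cerebral tissue (WM or GM).

## The model

**Intensity model.**  Within the brain mask, bias-corrected intensities
follow per-class Gaussian mixtures (defaults: 3 components for GM, 2 for
WM, 2 for CSF, 5 for "other"); mixtures, not single Gaussians, absorb
partial heterogeneity such as the hyperintense WMSA band inside the WM
class.  In neonatal T2, WM is brighter than GM (the reverse of adults), and
the deterministic initialization encodes this ordering (see *Numerical
choices*).

**Spatial priors.**  Atlas tissue probability maps are warped into subject
space (registration backend + inverse transform), floored at 1e-6 and
renormalized.  The floor matters: a hard zero prior would annihilate the
fused membership product at mask edges.  The E-step combines class
likelihoods with these priors by Bayes' rule.

**Bias field.**  A single multiplicative field shared by all classes,
`b = exp(X c)` on a 4×4×4 tensor discrete-cosine basis with the DC term
removed (64 − 1 = 63 coefficients); the global intensity scale lives in the
mixture means instead, which makes the model identifiable.  The coefficients
are re-fit each EM iteration by weighted least squares in the log domain
(weights `Σ r_k μ_k²/σ_k²`, the Gaussian precision mapped through the log
transform), and the update is **accepted only if the penalized
log-likelihood does not decrease** — combined with exact M-steps for the
Gaussian parameters this makes the objective monotone by construction,
which the test suite asserts per iteration.

**Fusion.**  The final membership multiplies the intensity-model posterior
and the atlas membership with exponents `p` and `q` and renormalizes.
`p = q = 1` (equal weights) is the default and the package makes no attempt
to tune them — no principled target exists for the weighting, and the
equal-weight choice is the one the detection threshold was calibrated under.
Where the products underflow to zero for every class (possible at mask
edges with near-one-hot priors), the voxel falls back to the intensity
model's membership and a count is attached to the result.

**Detection.**  A voxel is WMSA if (a) the joint segmentation's argmax is
WM or GM, and (b) its intensity is **at or above** `mean + α·SD` (population
SD) of all WM+GM voxels.  Statistics are computed once, hyperintense voxels
included — a deliberate single-pass rule; an iteratively re-estimated
threshold would be a different detector.  The threshold is applied to the
**bias-corrected** image: a single global threshold is only meaningful
after removing the multiplicative nonuniformity, and the unified model
estimates that field anyway.  α defaults to 1.4, the simulation-calibrated
optimum (below).

**Regions.**  Regional volumes are reported for the entire WM, the
periventricular slab (axial slices from the first appearance of the frontal
horns through the last midbody slice of the lateral ventricles), and the
centrum semiovale (the two axial slices above that last midbody slice).
Landmarks are user-supplied 0-based slice indices; on phantoms,
`suggest_region_spec()` derives them from interior (ventricular) CSF.
Automatic landmarking on clinical data is out of scope.

## The calibration world

`calibrate_alpha()` re-runs the full pipeline on simulated brains and picks
the α with maximum mean voxelwise **accuracy** against ground truth (Dice
and FPR are reported alongside; ties break to the smallest α).  The phantom
is a procedural stand-in for an anatomical model: nested ellipsoids
(peripheral CSF shell, cortical GM, WM interior), two elongated lateral
ventricles, class mean intensities CSF 400, WM 260, GM 190, WMSA 340,
Rician noise `sqrt((v+n1)² + n2²)` with `sd = mean(brain)/SNR`, and a
smooth multiplicative INU field rescaled to exactly 0.9–1.1 at the default
20% level.

**Lesion load is the one load-bearing free parameter.**  The accuracy
optimum balances the WM false-positive tail against the WMSA false-negative
tail, so it is governed by the WMSA:WM volume ratio.  A Gaussian analysis
of the threshold geometry shows that at a small focal load (a few percent
of WM) the optimum sits at or beyond α = 1.8 at every noise level, whereas
a diffuse load in the 15–25% range puts it at 1.3–1.4 *independent of SNR*.
Clinically, DEHSI is exactly that: diffuse periventricular/subcortical
signal change, reported in cohorts from small focal caps up to two-thirds
of the cerebral WM.  The generator's default is therefore a moderate
diffuse load of ~15% of WM (four periventricular and two centrum blobs,
carved to the WM compartment so they stop at ventricle and cortex
boundaries), fixed once before any calibration was run.  With it, the
calibration lands on α* = 1.4 at each SNR ∈ {10, 15, 20} individually —
reproducible via `scripts/acceptance.R` at 96³ in ~2 minutes.

Calibration phantoms use priors built from the phantom's own anatomy
(smoothed one-hot maps, WMSA counting as WM since the atlas knows only
CSF/GM/WM).  This deliberately excludes spatial-normalization error —
the same simplification as holding brain shape fixed across noise
realizations — so the calibrated α reflects the detector, not the
registration backend.

**What the phantom does not emulate** (so a green test does not establish
robustness to it): partial-volume mixing at tissue boundaries (single-label
voxels only), cortical folding, registration error between subject and
atlas, anatomy variation across subjects, scanner-specific intensity
scales, or WMSA intensity heterogeneity (all lesion voxels share one mean).

## Numerical choices

* **Initialization** is deterministic and seed-free: component means start
  at global intensity quantiles inside class-rank segments (GM 0.05–0.28,
  WM 0.45–0.80, CSF 0.92–0.99, other 0.02–0.98) encoding GM < WM < CSF;
  WM's upper segment end reaches into the hyperintense band so its second
  Gaussian can capture WMSA.  Tissue-class components start with variance
  `(sd(y)/3)²` so they stay in their band; "other" starts broad as the
  catch-all.  Prior-weighted initial moments were tried and rejected: with
  informative priors the WMSA band lies above WM's own weighted quantiles
  and both WM components collapse onto the normal-WM mode.
* **Variance floor** `(1e-3 × intensity range)²` keeps noise-free fits
  (exact class intensities) from collapsing to zero variance.
* **Ties** break to the lowest tissue code in `hard_segmentation()` (and
  "other" maps to background); α ties break to the smallest grid value.
* **Threshold inclusivity**: a voxel exactly at `mean + α·SD` is flagged.
* **INU synthesis** happens on a coarse grid (≥4 samples per FWHM) and is
  upsampled trilinearly — spectrally equivalent for such smooth fields and
  ~8× faster; the min/max rescale is applied after upsampling so the stated
  range is exact.
* **EM stopping**: relative log-likelihood change < 1e-5 or 50 iterations
  (typical convergence: 20–40); non-convergence returns the best fit with a
  warning flag recorded in the pipeline log.

## Testing notes and honest caveats

* The **bias-recovery** test injects a field from the package's own INU
  generator, but at FWHM 0.35 of the grid extent and rescaled to the 20%
  level over the brain mask.  Two measured reasons: the default 4×4×4 DCT
  basis resolves ~1.5 cycles/axis, so the rougher default field (FWHM 1/4)
  tests basis capacity rather than estimator correctness (recovery r ≈ 0.7);
  and the generator's whole-grid rescale leaves almost no in-mask variation
  (sd ≈ 0.005) against an estimation-noise floor of rms ≈ 0.002, capping
  attainable correlation regardless of quality.  Residual un-modelled INU at
  default roughness remains part of the calibration world and simply adds
  detection variance.
* The **regression-recovery** test bounds empirical 2-SE coverage at
  0.95 − 2 binomial SDs (≈ 0.93 over 500 replicates): a 2-SE interval's
  nominal coverage is ~94.8% at n = 38, so demanding ≥ 0.95 exactly would
  fail about half of all honest runs by construction.
* **Mean recovery at SNR 15** is assessed with informative priors (the
  model's operating configuration).  Under flat priors with noise the ML
  mixture legitimately re-partitions GM/WM boundary mass across classes
  (GM's weighted mean lands near 202 instead of 190); class identity
  without spatial priors is exactly the ambiguity the atlas resolves.
* Statistics are screened one at a time with two-sided p < 0.05 and **no
  multiple-comparison correction**, by design; the outcome module is a
  correlational screen, not a predictive model.

## Limitations

* The shipped registration backends (identity / translation / demons) are
  contract implementations; large-deformation diffeomorphic mapping is not
  re-implemented, and atlas quality with the demons backend on real data is
  untested.  The backend contract (invertible transforms, displacement-field
  serialization) is where a production registration tool would plug in.
* Atlas priors cover CSF/GM/WM only; WMSA is detected by thresholding, not
  modelled as an atlas class.
* No lesion-instance labelling: the output is a binary mask and regional
  volumes, not per-lesion statistics.
* Region landmarks on clinical data require the user to identify two
  ventricular slice indices.
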