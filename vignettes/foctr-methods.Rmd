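---
title: "Quantifying retinal perfusion and thickness from OCT volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal perfusion and thickness from OCT volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Systemic hypoxemia — for example during a sojourn at high altitude — changes
retinal microvascular perfusion and, over days, retinal thickness. Functional
OCT (fOCT) quantifies these responses by repeatedly imaging the macula with a
spectral-domain OCT scanner and reducing each 6 mm × 6 mm × 2 mm volume to
two scalars per eye and day:

* **rVPD** (retinal vascular perfusion density): the fraction of an en-face
  retinal area occupied by detected blood vessels, reported as a percentage
  of pixels (clinically often quoted in arbitrary units on the same scale);
* **RT** (retinal thickness): the mean axial distance between the inner
  limiting membrane (ILM) and the retinal pigment epithelium (RPE).

These imaging outcomes are then related to arterial blood gases — PaO₂,
PaCO₂, SaO₂, the stimulus index PaCO₂/PaO₂, and arterial oxygen content
CaO₂ = 1.36·Hb[g/dL]·(SaO₂/100) + 0.003·PaO₂ — with repeated-measures
statistics.

`foctr` implements this entire chain as composable R functions, and pairs it
with a synthetic scene generator so that every stage is testable against
known ground truth: clinical raw volumes of this kind are essentially never
public.

## The imaging pipeline

Given an `oct_volume` (array indexed fast axis × slow axis × depth, with
physical voxel spacing), `run_study()` executes per image:

1. **Quality control.** The axial mean-intensity profile's peak is compared
   with the standard deviation of the top vitreous band;
   `score = clamp(round(snr_db / 3), 0, 10)`. The commercial "signal
   strength" metric is proprietary, so this 0–10 mapping is the package's
   construction; images below 8/10 are rejected, mirroring the study
   rejection rule.
2. **Surface extraction** (`extract_surfaces()`). Per B-scan, each surface
   is a minimum-cost depth path under a hard smoothness constraint
   (default ≤ 2 voxels per A-scan step), found by dynamic programming. The
   ILM cost is the negative positive-going axial gradient; the RPE cost the
   negative axially smoothed intensity, restricted to at least 120 µm below
   the found ILM. Paths are median-filtered across B-scans and the ordering
   ILM < RPE is enforced. This is a self-contained stand-in for the
   proprietary clinical graph-search software, validated against synthetic
   ground truth rather than against that software's output.
3. **En-face projection** (`project_enface()`). Mean over the superficial
   slab, by default ILM to ILM + 120 µm (the acquisition literature does not
   pin down the projection band; it is configurable and recorded in
   provenance).
4. **Rigid coregistration** (`register_rigid()`). Rotation is searched
   coarse-to-fine (2°, 0.5°, 0.1° steps) with translation recovered at each
   candidate by phase correlation with parabolic sub-pixel refinement; both
   images are low-passed (25 µm) before scoring, since resampling a rotated
   candidate smooths speckle and would otherwise bias the correlation
   comparison toward nonzero rotations. In `run_study()`, near-integer
   shifts and sub-1.5° rotations are snapped, so that purely translational
   eye motion is realigned losslessly; the transform is recorded per image,
   while the scalar outcomes are computed in native space (rVPD is
   translation invariant, and resampled border fills would contaminate the
   probability histogram).
5. **Vessel segmentation** (`segment_vessels()`):
   * Gaussian denoising (10 µm) and gentle CLAHE (clip 1);
   * robust PCA by principal-component pursuit
     (`min ‖L‖* + λ‖S‖₁ s.t. L + S = M`, inexact augmented Lagrangian,
     λ = 1/√max(m,n)): the horizontal/vertical band artifacts and smooth
     background are low-rank, the vessels sparse; the sparse component
     carries forward;
   * multiscale Frangi vesselness on the sparse component (σ ∈ {15, 25, 40,
     60} µm, restricted at run time to scales at or above the pixel pitch —
     smaller σ differentiates single-pixel speckle, not structure; β = 0.5,
     c = 0.5 of the per-scale maximum Hessian norm, bright polarity);
   * suppression of circular artifacts: connected components of the
     super-threshold vesselness support with major/minor axis ratio < 2.5
     are zeroed;
   * **probability map** (`vessel_probability()`): vesselness above 0.1
     seeds the vascular support, extended by a 120 µm ellipse; inside that
     support the probability is the robustly normalized intensity (median
     → 0, 99.5th percentile → 1). The vesselness ridge is systematically
     narrower than the vessel lumen (and dashed at crossings), so
     thresholding raw vesselness cannot recover area fractions faithfully;
     anchoring the area decision on intensity within vessel-evidence
     support can;
   * **global thresholding** (`global_threshold()`): a single scalar for
     the whole image. The default mode derives the scalar from the image's
     probability histogram (Otsu); a fixed scalar (0.40), calibrated once
     on a synthetic batch by matching planted areas
     (`calibrate_threshold()`), is available as `threshold_method =
     "fixed"`. The per-image histogram mode proved markedly more robust to
     image-to-image intensity-scale variation than any single fixed scalar
     across the study's 3–8 % operating range (the acceptance script
     reports the realized recovery error); both modes apply identical
     parameters to every image.
6. **rVPD** = 100 · vessel pixels / total pixels (exact integer ratio);
   **RT** = mean of (RPE − ILM) × axial spacing over the scan area (a
   centred circular region is available). Per subject-day, the mean of the
   top-2/3 images by quality score is reported, ties broken toward earlier
   acquisitions.

### Why the threshold calibration is area-matching, not pooled Otsu

An earlier design derived the fixed threshold by pooling probabilities from
a calibration batch and applying Otsu once; on the final probability maps
that scalar lands well below the lumen boundary and systematically
under-segments wide vessels. Because the synthetic truth provides exact
planted areas, the calibration instead finds, per calibration volume, the
threshold whose mask area matches the planted fraction, and ships the
median. This uses ground truth only at calibration time, on a fixed batch,
never per test image.

## The synthetic scene generator

`generate_volume()` builds a macular cube with exact ground truth:

* **Geometry**: 6 × 6 × 2 mm; default grid 256 × 128 × 512 (half the
  acquisition sampling of 512 × 128 × 1024, which remains available via
  `grid_shape`). The en-face pixel is deliberately anisotropic
  (23.4 × 46.9 µm at half scale), as in the real raster.
* **Surfaces**: ILM depth and thickness are smoothed Gaussian random fields
  (correlation length 1.5 mm, amplitudes 30 µm and 10 µm) around a 300 µm
  mean thickness; real eyes were used in the original study, so anatomy
  generation is necessarily invented here.
* **Vasculature**: random branching walks in the en-face plane (4 roots,
  radii 35–70 µm, sparse branching), rasterized on a y-upsampled isotropic
  work grid so Euclidean distances are correct under anisotropic pixels,
  then extruded ~60 µm below the ILM. The cross-section is a flattened
  4th-order profile whose half-maximum sits exactly at the planted radius,
  so the recorded truth mask coincides with the profile's FWHM footprint —
  otherwise "planted area" would be ill-defined for soft-edged tubes. A
  planted `target_fraction` rescales all radii via an order statistic of
  the normalized distance map (exact pixel counts, ties broken
  deterministically); if the target would force radii below 0.8 of the
  pixel pitch, whole vessels are dropped instead (capillary-dropout
  analogue), keeping every planted vessel resolvable.
* **Artifacts**: a rank-≤2 band field (vertical + horizontal smooth stripe
  profiles) added inside the slab — by construction a recoverable target
  for the robust-PCA stage; circular Gaussian blobs in the vessel band as
  projection artifacts; multiplicative mean-preserving speckle
  (`exp(σZ − σ²/2)`, default σ = 0.2).
* **Repeated imaging**: `anatomy_seed` fixes the vasculature and surface
  shape while `seed` refreshes noise and artifacts, emulating repeated
  scans of the same retina. `run_study()` derives one anatomy per subject
  and fresh image seeds per acquisition, plus small integer eye-motion
  shifts.

What the generator does **not** emulate: interferometric speckle statistics,
motion artifacts within a scan, layer-resolved plexuses, pathology, or media
opacities. Passing the recovery suite therefore demonstrates algorithmic
correctness on idealized anatomy, not clinical-grade performance.

## The physiology cohort generator

`generate_cohort()` produces long-format subject × day physiology tables
whose day-wise means and SDs default to the study's printed group
statistics for days 0, 2 and 9 (arterial blood: SaO₂, PaCO₂, PaO₂, pH,
HCO₃⁻, Hb, Hct; cardiorespiratory: HR, blood pressure, ventilation). Two
conventions deserve note:

* `within_subject_sd` is a fraction ρ: each variable's day SD splits into a
  subject intercept (√(1−ρ²)·SD) and day-level noise (ρ·SD), so one scalar
  works across variables whose scales differ by orders of magnitude.
* Only MAP is printed for blood pressure, so SBP/DBP defaults are backed
  out assuming a 40 mmHg pulse pressure. The printed day-2 pH SD (0.2) is
  mirrored verbatim even though it is plausibly a typo for 0.02; it only
  affects generator realism, and nothing is asserted against it.

Planted outcomes tie imaging to physiology: the perfusion target
`rvpd_au = 4.4 − 0.0185·(PaO₂ − 84.8) + day offsets + subject effects`
(the slope reproduces a ~0.6-point rise when PaO₂ falls ~32 mmHg; the day-9
offset −0.35 emulates the observed normalization despite persistent
hypoxemia), and thickness targets carry day means 300.1/299.6/297.4 µm.
`run_study()` uses each subject-day's planted `rvpd_au` as that scene's
vessel fraction and `rt_um` as its mean thickness, so the imaging pipeline
and the statistics see one coherent within-subject structure.

## Statistics

* `rmcorr()` — the repeated-measures correlation: y regressed on x with
  subject-specific intercepts and one common slope;
  `r_rm = sign(slope)·√(SSx/(SSx+SSerr))`, df = observations − subjects − 1,
  p from F(1, df). Computed in closed form on within-subject centred data
  (equivalent to the ANCOVA normal equations, against which it is tested to
  1e−8). Type-I error is verified at 5 % ± 1.5 % over 2,000 null cohorts.
* `linregress()` — OLS via `lm()`, returning slope, intercept, R², p.
* `rm_anova_bonferroni()` — one-way repeated-measures ANOVA (complete-case:
  subjects missing a day are dropped with a message; mixed-model fallbacks
  for missing data are deliberately out of scope — the tidy tables export
  cleanly to `lme4`/`lmerTest` if needed) with paired t pairwise
  comparisons, p multiplied by the number of comparisons and capped at 1.
  Degenerate inputs with no day variation return F = 0 and unit p rather
  than 0/0.
* `day_deltas()`/`summarise_deltas()` — per-subject changes from a
  reference day, complete-case, then group mean ± SD.

All tests are two-tailed at α = 0.05. `tidy()`, `glance()` and `autoplot()`
methods expose fits in the broom/ggplot2 idiom.

## Numerical choices and degenerate inputs

* Indices are 1-based (R convention) with the depth axis increasing from
  vitreous to choroid; depth maps store 1-based voxel indices. All physical
  parameters are micrometres.
* Integer volumes (8/16-bit vendor exports) are promoted to doubles in
  [0, 1] on construction.
* The separable Gaussian convolution uses mirror-with-edge-duplication
  boundaries; kernels truncate at 4σ.
* RPCA iterations stop at a relative Frobenius reconstruction error of
  1e−6 (1e−7 for standalone use) or flag non-convergence; μ grows by 1.5
  per iteration from 1.25/‖M‖₂.
* A constant image short-circuits CLAHE (a flat field must not acquire
  structure) and yields an all-zero vesselness map.
* A zero noise floor (noise-free volume) clamps the quality score to 10
  with a warning rather than dividing by zero.
* Registration of a zero-variance image is an error; rotation estimates are
  reliable to about 0.1° on smooth fields, and the pipeline treats anything
  below 1.5° as zero to avoid needless resampling.

## Problem sizes

The packaged defaults run the full analysis at sizes a desktop handles
comfortably: a half-scale scene grid (256 × 128 × 512) for single-volume
recovery analyses, a 192 × 96 × 224 grid for the 18-subject × 3-day × 2-image
study analogue, 2,000 replicates for the type-I calibration and 500 for the
effect-size recovery. The full acquisition grid is one `grid_shape` argument
away; all accuracy statements in the test suite are made at the stated
sizes.

## Known limitations

* Recovery accuracy is quoted against the generator's idealized scenes; no
  claim transfers to clinical scans without validation against manual
  annotation.
* The thickness estimator's absolute accuracy degrades with coarse axial
  sampling (about ±half a voxel); day-to-day *differences* are much more
  precise because the extraction bias cancels.
* rVPD on the coarse study grid carries a uniform positive partial-volume
  bias; within-subject comparisons are unaffected.
* Sub-pixel vasculature (true capillaries) is outside the generator's and
  the segmenter's resolution by design.
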