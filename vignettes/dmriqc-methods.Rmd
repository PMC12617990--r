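---
title: "Methods: per-volume quality control for fetal diffusion MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-volume quality control for fetal diffusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmriqc)
```

## The problem and the model

A fetal diffusion acquisition is a 4D series: one 3D echo-planar volume
per (b-value, b-vector) pair. Fetal motion corrupts single volumes in
three distinguishable ways, and each has a cheap geometric or intensity
signature once a per-volume brain segmentation is available:

1. **Intra-volume motion during diffusion encoding** collapses the
   signal of individual slices ("black" or dropout slices). Signature:
   a slice whose mean in-mask intensity is far below the volume's mean
   in-mask intensity.
2. **Through-plane motion and contrast-dependent segmentation error**
   change the apparent segmented brain volume. Signature: the relative
   volume change against a reference volume.
3. **Gross displacement** pushes the brain against the imaging
   field of view. Signature: mask voxels on a FOV face.

Inter-volume motion is additionally quantified as the L2 norm between
consecutive brain centres of mass, but it is reported only: a volume
that merely *moved* can still be registered retrospectively, whereas a
volume with destroyed slices cannot, so only the three signatures above
make a volume red and eligible for re-acquisition.

### The b-value-dependent volume threshold

The segmented "brain" includes the CSF rim surrounding the fetal brain.
CSF has a high diffusivity (≈ 0.002 mm²/s), so its signal attenuates
quickly as b grows and the segmentation systematically shrinks at high
b — a volume change that is expected, not pathological. The tolerated
relative change therefore grows with b:

$$T(b) = \alpha\,(1 - e^{-b \cdot \mathrm{ADC}}) + f$$

with defaults α = 0.3, ADC = 0.002 mm²/s, f = 0.02. At b = 0 the
threshold is the fixed segmentation-error allowance f (2 %); it rises
monotonically with the CSF attenuation curve and saturates at
α + f = 0.32. α is a sensitivity/robustness trade-off: `alpha_sweep()`
reproduces the calibration experiment that justifies 0.3 by counting
per-volume disagreements against ground truth across a grid of α.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `alpha` | 0.3 | — | scale of the dynamic volume threshold |
| `f_offset` | 0.02 | fraction | b = 0 segmentation-error allowance |
| `adc_ref` | 0.002 | mm²/s | CSF diffusivity driving threshold saturation |
| `slice_deficit` | 0.35 | fraction | dropout cut: slice mean below (1 − 0.35) × volume mean |
| `min_mask_voxels_per_slice` | 5 | voxels | exempts unstable polar-cap slices |
| `boundary_fraction_tol` | 0 | fraction | cropping flag tolerance |
| `max_iterations` | 2 | — | re-acquisition cap (scan-time budget) |
| `reference_volume_policy` | `first` | — | `first` or `first_clean_b0` |

All intensity statistics are computed over in-mask voxels only: the
comparison is slice-of-brain against whole-brain, not slice-of-FOV,
which keeps the rule independent of background and maternal tissue.

## Numerical and design choices

* **Strict inequalities at both cuts.** A slice at exactly the 35 %
  deficit, or a volume change exactly at T(b), is clean. "Lower than"
  and "exceeds" read as strict; the acceptance bisection confirms the
  boundary sits at 35 % to within 0.1 %.
* **Two-sided volume change.** |ΔV|/V_ref is compared to T(b): both
  over- and under-segmentation indicate something went wrong.
* **Reference volume.** Default is the first dynamic. Because a
  corrupted reference poisons every comparison, the `first_clean_b0`
  policy falls back to the first b = 0 volume without dropout slices
  when volume 1 is itself dropout-flagged. The reference's own
  volume change is 0 by construction.
* **COM is the unweighted centroid of binary mask voxels** mapped
  through the affine (0-based voxel indices, world mm). An
  intensity-weighted centroid would drift with the diffusion contrast
  as b changes; the binary centroid does not. Rotation is not
  estimated — the L2 trace captures translation only.
* **Boundary contact counts all six FOV faces**, not only
  through-plane, since a brain can leave the FOV in-plane as well.
* **Probabilistic masks are binarized at 0.5.** A fixed, documented cut
  keeps verdicts reproducible across segmentation back-ends.
* **Priority score** = dropout-slice count + max(0, excess)/T(b) +
  1 if cropped; ties break on acquisition order. The source material
  prescribes *that* the list is prioritized but not *how*; this rule is
  this package's own design: severity-ordered, deterministic, and
  explainable from the verdict record. Empty-mask volumes receive a
  sentinel score of (slice count + 2) so they outrank any plausible
  dropout count while remaining finite (and JSON-serializable).
* **Volumes are re-planned whole**, never single slices or directions,
  and re-acquired volumes are matched to plan items by position and
  verified against (b-value, direction) within 1e-3.
* **ADC fitting** is weighted log-linear least squares (weights S²)
  after direction-averaging per shell; negative slopes clamp to 0, and
  slopes whose total decay over the sampled b range is below 1e-12 are
  snapped to exactly 0 (pure QR rounding noise on constant signals).
* **IVIM fitting is segmented** with `b_split = 200` s/mm²: D from the
  high-b tail, f from the intercept ratio against the measured S(0), D*
  by bounded 1-D least squares with D and f fixed. For compact 8-point
  protocols this is markedly more stable than a free 4-parameter fit;
  estimates are clamped to valid ranges rather than masked out so ROI
  statistics stay dense.
* **On-disk formats**: NIfTI-1 for images (sform affine, written
  unscaled in float64 so round trips are bitwise), FSL-style bval/bvec
  for gradient tables (signs preserved exactly as planned), JSON for QC
  reports (full precision), TSV + companion bval/bvec for the
  re-acquisition list. The scanner-side list format is this package's
  own convention; the manifest carries index, b-value, direction and
  rank so any consumer can reconstruct the plan.

## What the phantom emulates — and what it does not

`make_phantom()` builds an ellipsoidal parenchyma (IVIM parameters
S0 = 100, f = 0.1, D = 0.0012 mm²/s, D* = 0.05 mm²/s — mid-gestation
white-matter-like values) wrapped in a CSF rim (S0 = 150, f = 0,
D = 0.002 mm²/s), sampled on a 64 × 64 × 35 grid at 3 mm (the 35-slice
axial protocol at desk scale) with a 22-volume b-table (b = 0 plus
{10, 50, 80, 200, 400, 600, 1000} s/mm² × 3 orthogonal directions).
Signal decay is the two-compartment IVIM model per tissue class; noise,
when enabled, is Rician (magnitude MRI), with σ expressed relative to
parenchyma S0 so SNR 20 means `noise_sigma = 0.05`.

Injectable artifacts mirror the QC taxonomy: slice attenuation
(`dropout_slices`), whole-voxel COM shifts (`com_shift`), mask-only
volume drift emulating segmentation error (`volume_drift`, realized by
re-thresholding the ellipsoid radius field to hit the target voxel
count exactly — the anatomy never changes, only the "segmentation"),
and FOV clipping (`crop_shift`). COM shifts are restricted to whole
voxels so the scripted ground-truth displacement is exact to 1e-9 mm;
sub-voxel shifts would entangle discretization error with the motion
signal being tested.

The ground-truth red set is derived by running an independent,
loop-based reimplementation of the rules (`qc_bruteforce()`) on the
noiseless data. This is the same oracle used for the equivalence tests
against `run_qc()`, and it shares no code with the production path.

**Limits of a green test.** The phantom has homogeneous tissue classes,
no anatomy, no EPI/k-space artifact physics, no maternal motion model,
and its masks are exact by construction except where drift is injected.
A green phantom suite therefore establishes that the *rules and
plumbing* are correct, not that the thresholds are clinically optimal —
that calibration came from expert-annotated cohort data that desk-scale
testing cannot reproduce. One behavioural blind spot is worth knowing:
because the dropout rule is a ratio against the volume's own mean,
attenuating *many* (or all) slices of a volume simultaneously drags the
volume mean down with the slices and can evade the rule; such volumes
are usually caught by the volume-change rule instead, but a uniform
global attenuation is invisible to both (and to any purely ratio-based
check).

## Degenerate inputs

Empty masks yield missing features, force the verdict red, and are
excluded from the L2 trace (pairs recorded as `NA`). A series whose
masks are all empty is an error ("no usable volumes"), as is a
single-b-value series passed to `fit_adc()`. `mask_series` accepts any
values in [0, 1]; anything outside is an error rather than silently
clipped.

## Scaled-down testing

The default test suite and the acceptance criteria run phantoms on
~26 × 26 × 14 grids rather than the 64 × 64 × 35 default, and the
Rician sensitivity experiment uses 50 replicates at SNR 20. These sizes
keep the full suite under a minute while leaving every rule boundary
(threshold values, 35 % deficit, iteration cap, oracle equivalence)
exercised at full fidelity — the rules are resolution-independent
ratios and counts, so grid scale affects only granularity, not logic.
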