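---
title: "Shape-constrained vessel segmentation and flow quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-constrained vessel segmentation and flow quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Phase-contrast MR (PC-MR) encodes through-plane blood velocity in the image
phase: with velocity encoding limit VENC, a phase of $\pm\pi$ radians maps to
$\pm$VENC cm/s, so $v = \varphi/\pi \cdot \mathrm{VENC}$. Net flow volume
through a vessel requires a lumen delineation in **every** cardiac time
phase, which is tedious to draw by hand and fragile to automate: lumen
contrast against surrounding tissue is high during systole but collapses
during diastole, when the velocities (and hence inflow enhancement) are low.
A segmentation algorithm must therefore carry shape information through the
low-contrast part of the cycle.

`pcflow` implements a semi-automatic pipeline that requires a single manual
delineation in one time frame and constrains every automatically produced
contour by a PCA statistical shape model learned from reference
delineations.

## Pipeline

Given a series and one seed contour, `segment_series()` performs:

1. **Rigid motion tracking.** Integer-pixel shifts between adjacent
   magnitude frames by exhaustive normalized cross-correlation of the seed
   neighborhood (bounding box dilated by 4 px, shifts in
   $[-10, 10]^2$). Both frames are Gaussian-smoothed ($\sigma = 1.5$ px)
   before matching: an integer translation commutes with the smoothing, so
   the correlation peak is unbiased, while per-pixel noise — which otherwise
   dominates the patch energy in diastole and makes the tracked path random-walk —
   is strongly suppressed. Ties are broken toward the zero shift.
2. **Phase ordering.** The spatial median velocity inside the motion-tracked
   seed is computed per phase, and the phases are split into high- and
   low-velocity classes by one-dimensional 2-means. In 1-D the optimal
   2-means partition is a threshold in sorted order, so the split is computed
   exactly (global minimum of within-class sum of squares) rather than by
   iterative refinement — there is no random initialization anywhere in the
   pipeline. Processing starts at the seed phase if it lies in the high
   class, otherwise at the phase of maximum absolute median velocity;
   it walks forward through the contiguous high-velocity interval, back
   through its left half, then forward from the interval to the last phase
   and finally backward from the interval to phase 0. Every frame is thus
   initialized from an already-processed temporal neighbor, shifted by the
   tracked motion.
3. **Active contour.** Each frame's contour is deformed by a classic
   explicit snake on the magnitude image: external force
   $\nabla\lVert\nabla (G_\sigma * I)\rVert$ (gradient of the Gaussian edge
   map, $\sigma = 2$ px, normalized to unit maximum per frame and bilinearly
   interpolated), plus internal tension (discrete Laplacian) and rigidity
   (negative fourth difference) forces. Numerics: explicit Euler with step
   0.2, 100 iterations, 48 vertices resampled to uniform arc length after
   every step. These settings were chosen so that a contour seeded 2 px away
   from a high-contrast boundary converges well within one frame's
   iteration budget; they are exposed in `algorithm_params()`.
4. **Shape-constrained reconstruction.** The deformed contour is projected
   onto the PCA shape model (below) and each mode coefficient is clipped to
   $\pm 3\sqrt{\lambda_k}$. The comparison mode
   `curvature_mode = "curvature-force"` skips this step and relies on the
   snake's internal curvature forces alone, reproducing the behavior of
   earlier curvature-constrained methods.
5. **Diameter rescaling.** All contours are scaled about their centroid by a
   fixed factor (default 1.02). Edge detection on blurred lumen borders is
   biased inward — on the synthetic phantom the snake equilibrium sits
   $\approx 0.25$ px inside the true boundary — and the factor undoes that
   systematic bias. The default was calibrated with the grid harness
   (`optimize_parameters()`) on the synthetic phantom; on other data it
   should be re-optimized the same way.

When the seed phase is the starting phase, the manual contour is trusted:
it bypasses deformation and is only rescaled. Reconstruction once per frame
(not interleaved into the snake loop) is the default; interleaving is
available via `reconstruct_every_k_iterations` but measurably degraded
worst-phase overlap on the phantom when applied too frequently, because
frequent projection interrupts edge convergence.

## The shape model

Contours are parameterized radially: distances from a reference center to
the boundary along $n = 48$ equiangular rays, normalized by their mean. The
mean radius (size) and the center (pose) are removed before PCA and restored
on reconstruction, so the model constrains *shape only* — the diameter
rescale of step 5 stays an independent calibration.

The reference center is the **radial-harmonic center**: the point about
which the sampled radial profile has zero first circular harmonic
($\sum_i r_i (\cos\theta_i, \sin\theta_i) = 0$), found by a fixed-point
iteration started at the polygon area centroid. This choice, rather than the
area centroid itself, makes the construction self-consistent: deviations of
training shapes from the model mean live in the linear subspace with zero
mean and zero first harmonic, so PCA modes stay in that subspace, and
reconstruction preserves the center and mean radius *exactly* and is
idempotent (verified to 1e-9 in the tests). Rays must meet the boundary
exactly once — non-star-shaped contours are rejected with the offending ray
angle, which is the right failure mode for great-vessel lumina.

Models are trained per vessel (separate aorta and pulmonary models), pooling
all cardiac phases of all training subjects; a pooled model applies at any
phase during the per-frame processing loop. No rotational alignment is done
before PCA: slice orientations follow clinical protocol, so in-plane vessel
orientation is anatomically consistent and rotation is informative. The
retained mode count is the smallest $k$ reaching 95% cumulative explained
variance; modes with vanishing eigenvalue get a zero clip bound (the
coefficient is forced to 0), avoiding division by zero in SD units. Strict
constraints (few modes, tight clip) trade the ability to reproduce complex
shapes for robustness; the default follows the strict end of that trade-off.

## Flow quantification

A pixel belongs to a contour's interior when its center lies inside the
polygon (even-odd rule); the same rasterization is used for flow sums,
median velocities and Dice overlap, so all quantities are mutually
consistent. Per-phase flow is $\sum_i v_i \, \Delta A$ (cm$^3$/s = ml/s)
over interior pixel centers; net volume is the time-sum
$\sum_t Q_t \,\Delta t$. Cardiac index is net aortic volume × heart rate /
BSA; Qp/Qs is the ratio of pulmonary to aortic net volume.

Background phase offsets are removed by fitting a plane $a + bx + cy$ by
least squares to the *time-averaged* velocity over static tissue and
subtracting it from every frame. The default static-tissue rule — temporal
velocity SD below its 25th percentile and mean magnitude above its median —
excludes both flowing blood and air; a user mask can override it.
Velocities are taken at face value with $|v| \le$ VENC; no unwrapping is
attempted, matching acquisitions whose VENC is chosen above the peak
velocity.

## The synthetic phantom

`generate_phantom_series()` renders a moving, pulsating circular lumen with
analytic ground truth. Defaults describe one fixed set of study conditions:

| quantity | default | what it emulates |
|---|---|---|
| lumen radius | 13 mm | a 26 mm inner-diameter tube |
| grid, spacing | 96×96 px, 1 mm | typical in-plane resolution |
| phases, dt, RR | 30, 30 ms, 900 ms | retrospectively gated cine |
| VENC | 200 cm/s | routine great-vessel protocol |
| velocity profile | parabolic | laminar tube flow; $Q = \tfrac{1}{2} v_{peak} \pi R^2$ |
| systolic pulse | half-sine over 35% of RR, diastolic baseline 3 cm/s | arterial waveform |
| in-plane motion | 2.5 / 1.5 mm loop | cardiac displacement of the vessel |
| radius pulsation | +8% in systole | vessel compliance |
| lumen/background contrast | 3.0 systole → 1.1 diastole | diastolic contrast drop |
| magnitude noise | Gaussian, SD 0.10 of background | SNR ≈ 10 |
| phase noise | SD 0.02 rad | velocity noise ≈ 1.3 cm/s |
| background plane | 0.3 + 0.005x − 0.004y cm/s | eddy-current offset |
| adjacent structure | bright disk, r = 8 mm, ~5 px gap, co-moving | neighboring vessel the contour must not expand into |

The diastolic contrast floor of 1.1 together with SNR 10 puts the diastolic
edge at the detection limit — the regime in which segmentation must lean on
shape constraints — and the adjacent bright structure provides the
"erroneous expansion" temptation that motivates them. Magnitude partial
volume is emulated by a 1 px Gaussian blur; noise is Gaussian (adequate at
these SNRs and keeps the oracles simple). A requested stroke volume
(`target_volume`) scales the velocity waveform using the closed-form volume,
which is exact because flow is linear in the waveform.

What the phantom does **not** emulate: k-space sampling and its artefacts,
Rician magnitude statistics at low SNR, eddy-current nonlinearity,
respiratory motion, gating jitter, through-plane motion, and non-circular or
pathologically shaped lumina. Passing the synthetic acceptance checks
therefore demonstrates correctness of the mechanics (tracking, ordering,
deformation, reconstruction, flow integration) under controlled conditions,
not clinical-grade accuracy on hospital data.

The training-set generator produces per-subject time-resolved delineations
from a family of ellipses (aspect 0.85–1.0, mild orientation jitter, 3rd/4th
boundary harmonics up to 3%, +8% systolic size pulse) — enough structured
variation for a meaningful PCA without copying the phantom's exact shapes.

## Parameter optimization and evaluation

`optimize_parameters()` scores a grid of snake/shape settings on training
series with reference segmentations: for each combination the best diameter
`scale_factor` is found by a nested 1-D sweep (segmentation is run once at
unit scale; rescaling commutes with the earlier steps, so the sweep is
cheap), and the score is $\overline{\mathrm{Dice}} - \lambda \cdot
\mathrm{SD}(\mathrm{Dice})$ over all training frames, with $\lambda = 1$ by
default — a large mean overlap *without overexpressed variability*. The
variability penalty is the package's explicit operationalization of that
qualitative criterion. Failing combinations score $-\infty$ and stay in the
log. `initialization_sweep()` re-runs the full pipeline seeded at
equidistant RR fractions and reports volume and Dice per seed — the
stability analysis that justifies trusting a single manual delineation.

Bland–Altman agreement (`bland_altman()`) reports bias (mean difference),
variability (one SD) and 95% limits of agreement (bias ± 1.96 SD).

## Numerical choices and degenerate inputs

* All-equal median velocities make the 2-means split degenerate; every phase
  is then treated as high-velocity, with a warning.
* Featureless tracking patches leave all correlations equal; the tie-break
  returns the zero shift.
* Snake output is not forced to be simple: transient self-intersections
  under heavy noise are resolved by the reconstruction step, which rebuilds
  the contour from a radial profile. A contour that collapses below 3
  interior pixels raises an error naming the phase.
* Contours are stored with positive (counter-clockwise) shoelace
  orientation; inputs are reoriented on construction.
* The pipeline is deterministic end to end: identical inputs, parameters and
  seeds yield bit-identical results. Phantom noise is the only random
  element and is fully reproducible from `seed`.

## Problem sizes used by the test-suite and acceptance runs

Unit tests use an 8-phase 96×96 phantom; the acceptance checks use the
default 30-phase phantom, a 5-point stroke-volume sweep (12–90 ml), a
20-point initialization sweep, and a reduced 12-phase configuration for the
end-to-end determinism check. These sizes were chosen to exercise every
stage at full fidelity while keeping a complete run in the minutes range on
one CPU.

## Known limitations

* On the single-vessel phantom the measured advantage of the PCA constraints
  over the curvature-force comparison at the *worst* phase is small (both
  methods inherit the same motion-tracked initialization, which dominates
  the worst-phase error); the advantage reported for clinical images — where
  adjacent anatomy and artefacts mislead unconstrained contours far more
  strongly — cannot be reproduced from synthetic data alone.
* The radial parameterization requires star-shaped lumina; dissections or
  strongly lobed cross-sections are out of scope.
* DICOM input is not implemented; series enter through the documented array
  container (`write_series()` / `read_series()`).
* Only in-plane rigid motion is modeled; through-plane motion and 4D flow
  are out of scope.
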