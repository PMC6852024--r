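# pcflow

Semi-automatic, shape-constrained segmentation of great-vessel cross-sections
in time-resolved 2D phase-contrast MR (PC-MR) images, and the downstream
blood-flow quantities clinicians actually read: net flow volume, cardiac
index, and the pulmonary-to-systemic flow ratio Qp/Qs.

## Who this is for

Measuring flow in the ascending aorta or main pulmonary artery requires a
lumen contour in *every* cardiac time phase. Manual delineation is slow, and
naive automatic contours fail during diastole, when the low blood velocity
removes the inflow contrast between lumen and surrounding tissue. `pcflow`
targets researchers who need robust, reproducible time-resolved vessel
segmentation from a **single** manual delineation, together with the flow
analysis and an end-to-end synthetic validation harness.

## The method

The phase image encodes through-plane velocity as
`v = phi / pi * VENC` (cm/s). From one seed contour the pipeline runs:

1. **Rigid motion tracking** — integer-pixel shifts between adjacent
   magnitude frames by exhaustive normalized cross-correlation of the
   (smoothed) vessel neighborhood.
2. **Phase ordering** — the spatial median velocity inside the
   motion-tracked seed is clustered into high/low classes by exact 1-D
   2-means; processing starts inside the high-velocity (systolic) interval,
   where contrast is best, and spreads outward so every frame is initialized
   from an already-segmented temporal neighbor.
3. **Active contour** — a classic explicit snake deforms the initialization
   under the gradient of a Gaussian edge map plus tension/rigidity forces.
4. **Shape-constrained reconstruction** — the contour's radial profile
   `r(theta_i)` (48 equiangular rays, scale- and pose-normalized) is
   projected onto a PCA shape model `r = rbar + Phi b` learned from
   reference delineations, with each coefficient clipped to
   `|b_k| <= 3 sqrt(lambda_k)`. This carries plausible vessel shape through
   the low-contrast diastolic frames.
5. **Diameter rescaling** — a fixed calibration factor (default 1.02)
   undoes the inward bias of edge detection on blurred lumen borders.

Flow per phase is `Q_t = sum_i v_i dA` over interior pixel centers (ml/s),
net volume `SV = sum_t Q_t dt`, cardiac index `SV x HR / BSA`, and
`Qp/Qs = SV_pulmonary / SV_aorta`. A linear background-phase plane fitted on
static tissue is removed first. Everything is deterministic: no random
initialization anywhere.

A synthetic pulsatile phantom (26 mm tube, parabolic profile, systolic
pulse, in-plane motion, diastolic contrast drop, adjacent bright structure,
Gaussian noise) provides analytic ground truth for contours, per-phase flow
and stroke volume, so the whole pipeline is testable without any data
download. See the methods vignette (`vignettes/pcflow-methods.Rmd`) for the
model, parameters, and design decisions.

## Worked example

```r
library(pcflow)

# synthetic acquisition with known truth: 30 phases, 96x96 px, VENC 200
gen <- generate_phantom_series(phantom_spec(seed = 1))

# train the statistical shape model on synthetic reference delineations
model <- fit_shape_model(generate_training_set(12, "aorta", seed = 7),
                         vessel_label = "aorta")

# one manual delineation at 20% of the RR interval seeds the whole series
seed_contour <- gen$truth$contours[[7]]
seg <- segment_series(gen$series, seed_contour, model, algorithm_params())

flow <- quantify_flow(gen$series, seg, bsa = 1.9)
print(flow)
#> <pc_flow> net volume 76.8 ml over 30 phases, HR 67 bpm, CI 2.69 l/min/m^2

gen$true_net_volume
#> [1] 76.84139

dv <- sapply(1:30, function(i) dice(seg$contours[[i]], gen$truth$contours[[i]], c(96, 96)))
median(dv)
#> [1] 0.9560507
```

The measured stroke volume (76.8 ml) agrees with the analytic truth
(76.84 ml) to within 0.1 ml, and the median Dice overlap with
the true lumen across all 30 phases is 0.956 despite the diastolic contrast
drop and SNR-10 noise. A command-line wrapper with `simulate`,
`train-shape-model`, `segment`, `quantify`, `evaluate` and `run-all`
subcommands lives at `inst/cli/pcflow.R`.

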