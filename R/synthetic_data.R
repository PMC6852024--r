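# Synthetic pulsatile-vessel phantom with analytic ground truth.
#
# Emulates a gated 2D PC-MR acquisition of a single vessel cross-section:
# a moving, pulsating lumen with a systolic flow pulse, cycle-dependent
# lumen/background contrast (diastolic contrast drop), partial-volume blur,
# Gaussian noise on magnitude and phase, and a linear background-phase
# offset. Flow volume ground truth is available in closed form.

# run code under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# half-sine systolic pulse over the first `systole_frac` of the cycle
systolic_pulse <- function(T_, systole_frac = 0.35) {
  f <- (seq_len(T_) - 1L) / T_
  ifelse(f < systole_frac, sin(pi * f / systole_frac), 0)
}

#' Specification of the synthetic pulsatile phantom
#'
#' Defaults mirror a great-vessel acquisition: a 26 mm inner-diameter tube
#' (13 mm radius), 30 phases of 30 ms over a 900 ms cycle, VENC 200 cm/s,
#' 1 mm isotropic pixels, a half-sine systolic velocity pulse with a small
#' diastolic baseline, in-plane motion of a few mm, and lumen/background
#' contrast falling from 3.0 in systole toward 1.2 in diastole (the diastolic
#' contrast drop that forces reliance on shape constraints).
#'
#' @param grid image size `c(H, W)` pixels.
#' @param pixel_spacing `(dy, dx)` mm.
#' @param n_phases_t number of cardiac phases T.
#' @param temporal_resolution ms per phase.
#' @param venc cm/s.
#' @param rr_interval ms.
#' @param base_radius lumen radius, mm.
#' @param radius_amp fractional systolic radius increase (radius waveform is
#'   `1 + radius_amp * pulse`); overridden by `radius_waveform`.
#' @param radius_waveform optional explicit length-T multiplicative waveform.
#' @param center_amplitude `(ax, ay)` mm amplitude of in-plane motion.
#' @param center_path optional explicit T x 2 matrix of center offsets (mm)
#'   from the grid center.
#' @param peak_velocity systolic peak (centerline) velocity, cm/s.
#' @param diastolic_velocity small diastolic baseline velocity, cm/s.
#' @param flow_waveform optional explicit length-T peak-velocity waveform
#'   (cm/s), overriding `peak_velocity`/`diastolic_velocity`.
#' @param target_volume optional net flow volume (ml); when given, the flow
#'   waveform is scaled so the analytic stroke volume equals it.
#' @param velocity_profile `"parabolic"` (Poiseuille) or `"plug"`.
#' @param contrast_range `(lo, hi)` lumen/background magnitude ratio at zero /
#'   peak flow.
#' @param noise_sigma_magnitude Gaussian noise SD on magnitude (background
#'   level is 1).
#' @param noise_sigma_phase Gaussian noise SD on phase, radians.
#' @param background_plane `(a, b, c)`: background velocity offset
#'   `a + b*x + c*y` in cm/s over pixel coordinates.
#' @param distractor adjacent static anatomy (e.g. a neighboring vessel):
#'   list with `offset` (mm from the grid center), `radius` (mm) and `level`
#'   (magnitude). Its strong, flow-independent edge next to the lumen is what
#'   tempts an unconstrained contour to expand into adjacent anatomy when the
#'   lumen contrast drops in diastole. `NULL` disables it.
#' @param systole_frac fraction of the cycle occupied by the systolic pulse.
#' @param vessel_label vessel label carried by the series.
#' @param seed RNG seed for the noise realizations.
#' @return A list of class `pc_phantom_spec`.
#' @export
phantom_spec <- function(grid = c(96L, 96L),
                         pixel_spacing = c(1, 1),
                         n_phases_t = 30L,
                         temporal_resolution = 30,
                         venc = 200,
                         rr_interval = 900,
                         base_radius = 13,
                         radius_amp = 0.08,
                         radius_waveform = NULL,
                         center_amplitude = c(2.5, 1.5),
                         center_path = NULL,
                         peak_velocity = 120,
                         diastolic_velocity = 3,
                         flow_waveform = NULL,
                         target_volume = NULL,
                         velocity_profile = c("parabolic", "plug"),
                         contrast_range = c(1.1, 3.0),
                         noise_sigma_magnitude = 0.10,
                         noise_sigma_phase = 0.02,
                         background_plane = c(0.3, 0.005, -0.004),
                         distractor = list(offset = c(24, 10), radius = 8,
                                           level = 2.0),
                         systole_frac = 0.35,
                         vessel_label = "aorta",
                         seed = 1L) {
  velocity_profile <- match.arg(velocity_profile)
  T_ <- as.integer(n_phases_t)
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  pulse <- systolic_pulse(T_, systole_frac)
  if (is.null(radius_waveform)) radius_waveform <- 1 + radius_amp * pulse
  if (length(radius_waveform) != T_ || any(radius_waveform <= 0)) {
    stop("radius_waveform must be length T and positive")
  }
  if (is.null(flow_waveform)) {
    flow_waveform <- pmax(peak_velocity * pulse, diastolic_velocity)
  }
  if (length(flow_waveform) != T_) stop("flow_waveform must have length T")
  if (is.null(center_path)) {
    f <- (seq_len(T_) - 1L) / T_
    center_path <- cbind(center_amplitude[1L] * sin(2 * pi * f),
                         center_amplitude[2L] * (1 - cos(2 * pi * f)) / 2)
  }
  center_path <- matrix(as.numeric(center_path), T_, 2L)
  spec <- structure(
    list(
      grid = as.integer(grid), pixel_spacing = as.numeric(pixel_spacing),
      n_phases_t = T_, temporal_resolution = temporal_resolution,
      venc = venc, rr_interval = rr_interval,
      base_radius = base_radius, radius_waveform = radius_waveform,
      center_path = center_path, flow_waveform = flow_waveform,
      velocity_profile = velocity_profile, contrast_range = contrast_range,
      noise_sigma_magnitude = noise_sigma_magnitude,
      noise_sigma_phase = noise_sigma_phase,
      background_plane = as.numeric(background_plane),
      distractor = distractor,
      vessel_label = vessel_label, seed = as.integer(seed)
    ),
    class = "pc_phantom_spec"
  )
  if (!is.null(target_volume)) {
    spec$flow_waveform <- spec$flow_waveform *
      (target_volume / analytic_flow(spec)$net_volume)
  }
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (max(abs(spec$flow_waveform)) > spec$venc) {
    stop("aliasing: peak velocity ", round(max(abs(spec$flow_waveform)), 1),
         " cm/s exceeds VENC ", spec$venc, " cm/s")
  }
  r_px <- spec$base_radius * max(spec$radius_waveform) /
    min(spec$pixel_spacing)
  ctr <- phantom_centers_px(spec)
  margin <- min(ctr[, 1L], spec$grid[2L] - 1 - ctr[, 1L],
                ctr[, 2L], spec$grid[1L] - 1 - ctr[, 2L]) - r_px
  if (margin < 2) stop("lumen comes within 2 px of the image border")
  invisible(spec)
}

# per-phase lumen center in pixel coordinates
phantom_centers_px <- function(spec) {
  cx0 <- (spec$grid[2L] - 1) / 2
  cy0 <- (spec$grid[1L] - 1) / 2
  cbind(cx0 + spec$center_path[, 1L] / spec$pixel_spacing[2L],
        cy0 + spec$center_path[, 2L] / spec$pixel_spacing[1L])
}

# closed-form flow: parabolic profile integrates to v_peak/2 * pi R^2,
# plug profile to v * pi R^2 (R in cm)
analytic_flow <- function(spec) {
  R_cm <- spec$base_radius * spec$radius_waveform / 10
  area <- pi * R_cm^2
  per_phase <- switch(spec$velocity_profile,
    parabolic = spec$flow_waveform / 2 * area,
    plug = spec$flow_waveform * area
  )
  list(per_phase = per_phase,
       net_volume = sum(per_phase) * spec$temporal_resolution / 1000)
}

#' Generate a synthetic PC-MR phantom series with ground truth
#'
#' Renders magnitude and velocity-encoded phase stacks for the phantom in
#' `spec` and returns them with the analytic ground truth: per-phase lumen
#' boundary contours, the per-phase flow (ml/s) and the net flow volume (ml),
#' both integrated in closed form from the velocity profile. Magnitude frames
#' are Gaussian-blurred by 1 px for partial volume; seeded Gaussian noise is
#' added to both stacks. Identical specs (including seed) give bit-identical
#' output.
#'
#' @param spec a [phantom_spec()].
#' @return List with `series` ([pc_series()]), `truth` ([pc_segmentation()]),
#'   `true_flow_per_phase` (ml/s), `true_net_volume` (ml), and `spec`.
#' @export
generate_phantom_series <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "pc_phantom_spec"))
  validate_phantom_spec(spec)
  H <- spec$grid[1L]; W <- spec$grid[2L]; T_ <- spec$n_phases_t
  centers <- phantom_centers_px(spec)
  xs <- matrix(rep(0:(W - 1L), each = H), H, W)
  ys <- matrix(rep(0:(H - 1L), times = W), H, W)
  pulse_norm <- spec$flow_waveform / max(abs(spec$flow_waveform))
  contrast <- spec$contrast_range[1L] +
    diff(spec$contrast_range) * abs(pulse_norm)
  plane <- spec$background_plane[1L] + spec$background_plane[2L] * xs +
    spec$background_plane[3L] * ys
  # the adjacent structure rides the same in-plane motion as the vessel
  # (mediastinal anatomy moves together), so it recurs per phase below
  has_distractor <- !is.null(spec$distractor)
  magnitude <- array(0, dim = c(T_, H, W))
  phase <- array(0, dim = c(T_, H, W))
  truth_contours <- vector("list", T_)
  angles <- 2 * pi * (0:63) / 64
  with_seed(spec$seed, {
    for (t in seq_len(T_)) {
      R_mm <- spec$base_radius * spec$radius_waveform[t]
      Rx <- R_mm / spec$pixel_spacing[2L]
      Ry <- R_mm / spec$pixel_spacing[1L]
      dx <- (xs - centers[t, 1L]) / Rx
      dy <- (ys - centers[t, 2L]) / Ry
      r2 <- dx^2 + dy^2
      lumen <- r2 <= 1
      m <- matrix(1, H, W)
      if (has_distractor) {
        dc <- centers[t, ] +
          spec$distractor$offset / rev(spec$pixel_spacing)
        dr2 <- (spec$distractor$radius / spec$pixel_spacing[2L])^2
        m[(xs - dc[1L])^2 + (ys - dc[2L])^2 <= dr2] <- spec$distractor$level
      }
      m[lumen] <- contrast[t]
      m <- EBImage::gblur(m, sigma = 1)
      magnitude[t, , ] <- m +
        matrix(stats::rnorm(H * W, 0, spec$noise_sigma_magnitude), H, W)
      v <- matrix(0, H, W)
      if (spec$velocity_profile == "parabolic") {
        v[lumen] <- spec$flow_waveform[t] * (1 - r2[lumen])
      } else {
        v[lumen] <- spec$flow_waveform[t]
      }
      ph <- pi * (v + plane) / spec$venc +
        matrix(stats::rnorm(H * W, 0, spec$noise_sigma_phase), H, W)
      phase[t, , ] <- pmin(pmax(ph, -pi), pi - 1e-9)
      truth_contours[[t]] <- pc_contour(
        cbind(centers[t, 1L] + Rx * cos(angles),
              centers[t, 2L] + Ry * sin(angles)),
        phase_index = t - 1L, check = FALSE
      )
    }
  })
  magnitude <- pmax(magnitude, 0)
  series <- pc_series(
    magnitude, phase,
    pixel_spacing = spec$pixel_spacing,
    temporal_resolution = spec$temporal_resolution,
    venc = spec$venc, rr_interval = spec$rr_interval,
    vessel_label = spec$vessel_label
  )
  truth <- pc_segmentation(truth_contours, seed_phase = 0L)
  af <- analytic_flow(spec)
  list(series = series, truth = truth,
       true_flow_per_phase = af$per_phase,
       true_net_volume = af$net_volume,
       spec = spec)
}

#' Generate a synthetic training set of reference delineations
#'
#' Emulates a pool of per-subject, time-resolved manual delineations for
#' shape-model training: ellipses with subject-specific aspect ratio and mild
#' orientation jitter, low-order boundary harmonics, and a systolic size
#' pulse. Fully deterministic given `seed`.
#'
#' @param n_subjects number of subjects (>= 2 recommended).
#' @param vessel_label label carried by the contours' segmentations.
#' @param seed RNG seed.
#' @param n_phases_t cardiac phases per subject.
#' @param aspect_range range of the minor/major axis ratio across subjects.
#' @param harmonic_amp maximum amplitude of 3rd/4th-order boundary harmonics
#'   (fraction of radius); 0 disables them.
#' @param pulsation fractional systolic radius increase; 0 freezes the cycle.
#' @param radius_range range of base radii, pixels.
#' @param rotation_jitter half-width of the per-subject orientation jitter,
#'   radians (vessel orientation is anatomically consistent, so jitter is
#'   small; 0 disables).
#' @return List of `n_subjects` [pc_segmentation()] objects.
#' @export
generate_training_set <- function(n_subjects, vessel_label = "aorta",
                                  seed = 1L, n_phases_t = 20L,
                                  aspect_range = c(0.85, 1),
                                  harmonic_amp = 0.03,
                                  pulsation = 0.08,
                                  radius_range = c(10, 15),
                                  rotation_jitter = 0.15) {
  stopifnot(n_subjects >= 1L)
  T_ <- as.integer(n_phases_t)
  pulse <- systolic_pulse(T_)
  angles <- 2 * pi * (0:63) / 64
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      r0 <- stats::runif(1L, radius_range[1L], radius_range[2L])
      aspect <- stats::runif(1L, aspect_range[1L], aspect_range[2L])
      rot <- stats::runif(1L, -rotation_jitter, rotation_jitter)
      a3 <- stats::runif(1L, 0, harmonic_amp)
      a4 <- stats::runif(1L, 0, harmonic_amp * 2 / 3)
      p3 <- stats::runif(1L, 0, 2 * pi)
      p4 <- stats::runif(1L, 0, 2 * pi)
      contours <- lapply(seq_len(T_), function(t) {
        size <- 1 + pulsation * pulse[t]
        th <- angles - rot
        r_ell <- aspect / sqrt((aspect * cos(th))^2 + sin(th)^2)
        r <- r0 * size * r_ell *
          (1 + a3 * cos(3 * th + p3) + a4 * cos(4 * th + p4))
        pc_contour(cbind(48 + r * cos(angles), 48 + r * sin(angles)),
                   phase_index = t - 1L, check = FALSE)
      })
      pc_segmentation(contours, seed_phase = 0L)
    })
  })
}
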