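# Shared fixtures, built in code and memoized so expensive objects (phantom
# series, trained shape models) are constructed once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

circle_contour <- function(radius, center = c(0, 0), n = 64L, phase = 0L) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  pc_contour(cbind(center[1L] + radius * cos(th),
                   center[2L] + radius * sin(th)),
             phase_index = phase)
}

# axis-aligned rectangle whose interior pixel centers are exactly
# x0..x1 times y0..y1
rect_contour <- function(x0, x1, y0, y1, phase = 0L) {
  pc_contour(cbind(c(x0 - 0.45, x1 + 0.45, x1 + 0.45, x0 - 0.45),
                   c(y0 - 0.45, y0 - 0.45, y1 + 0.45, y1 + 0.45)),
             phase_index = phase)
}

# default shape model trained on the synthetic delineation family
aorta_model <- function() {
  fixture("aorta_model", function() {
    fit_shape_model(generate_training_set(12L, "aorta", seed = 7L),
                    vessel_label = "aorta")
  })
}

# the default pulsatile phantom (full study conditions)
default_phantom <- function() {
  fixture("default_phantom", function() generate_phantom_series(phantom_spec()))
}

# small, fast phantom for unit tests: fewer phases, no distractor
tiny_spec <- function(...) {
  defaults <- list(n_phases_t = 8L, temporal_resolution = 110,
                   rr_interval = 900, distractor = NULL,
                   noise_sigma_magnitude = 0, noise_sigma_phase = 0,
                   background_plane = c(0, 0, 0),
                   center_amplitude = c(0, 0), radius_amp = 0)
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

# brute-force 1-D two-class clustering oracle: all 2^T assignments,
# minimal within-class sum of squares; high class has the larger mean
exhaustive_two_partition <- function(x) {
  T_ <- length(x)
  best <- NULL; best_sse <- Inf
  for (mask in 1:(2^T_ - 2L)) {
    g <- as.logical(bitwAnd(mask, bitwShiftL(1L, 0:(T_ - 1L))))
    sse <- sum((x[g] - mean(x[g]))^2) + sum((x[!g] - mean(x[!g]))^2)
    if (sse < best_sse - 1e-12) { best_sse <- sse; best <- g }
  }
  hi <- if (mean(x[best]) >= mean(x[!best])) best else !best
  sort(which(hi) - 1L)
}

dice_vec <- function(seg, truth, grid) {
  vapply(seq_along(seg$contours), function(i) {
    dice(seg$contours[[i]], truth$contours[[i]], grid)
  }, numeric(1L))
}

near_circle_model <- function() {
  fixture("near_circle_model", function() {
    fit_shape_model(
      generate_training_set(8L, "aorta", seed = 11L,
                            aspect_range = c(0.95, 1), harmonic_amp = 0.01),
      vessel_label = "aorta"
    )
  })
}
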