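# Flow quantification: background-phase correction, per-phase flow, net flow
# volume, cardiac index, Qp/Qs.

#' Linear background-phase correction
#'
#' Fits a plane `v = a + b*x + c*y` by least squares to the time-averaged
#' velocity over static-tissue pixels and subtracts it from every cardiac
#' phase, removing the spatially linear velocity offset left by eddy currents
#' and concomitant gradients.
#'
#' @param vel a `pc_velocity`.
#' @param static_mask logical H x W matrix of static-tissue pixels (>= 10
#'   pixels, not collinear). See [static_tissue_mask()] for the default rule.
#' @return A corrected `pc_velocity` (`corrected = TRUE`), with the fitted
#'   plane coefficients attached as attribute `"plane"` (a, b, c).
#' @export
linear_background_correction <- function(vel, static_mask) {
  stopifnot(inherits(vel, "pc_velocity"), is.logical(static_mask))
  d <- dim(vel$velocity)
  if (!identical(dim(static_mask), d[2:3])) {
    stop("static_mask must match the image dimensions")
  }
  idx <- which(static_mask, arr.ind = TRUE)
  if (nrow(idx) < 10L) stop("static mask needs at least 10 pixels")
  x <- idx[, 2L] - 1; y <- idx[, 1L] - 1
  X <- cbind(1, x, y)
  if (qr(X)$rank < 3L) stop("static mask pixels are collinear; cannot fit a plane")
  vbar <- apply(vel$velocity, c(2L, 3L), mean)
  coef <- qr.solve(X, vbar[idx])
  xs <- matrix(rep(0:(d[3L] - 1L), each = d[2L]), d[2L], d[3L])
  ys <- matrix(rep(0:(d[2L] - 1L), times = d[3L]), d[2L], d[3L])
  plane <- coef[1L] + coef[2L] * xs + coef[3L] * ys
  out <- vel$velocity - rep(plane, each = d[1L])
  structure(
    list(velocity = array(out, dim = d), corrected = TRUE),
    class = "pc_velocity", plane = unname(coef)
  )
}

#' Default static-tissue mask
#'
#' Selects pixels that are both temporally quiet and tissue-like: temporal
#' velocity standard deviation below its 25th percentile and time-averaged
#' magnitude above its 50th percentile (excluding air and flowing blood).
#'
#' @param series a [pc_series()].
#' @param vel optional precomputed `pc_velocity` for the series.
#' @return Logical H x W mask.
#' @export
static_tissue_mask <- function(series, vel = NULL) {
  stopifnot(inherits(series, "pc_series"))
  if (is.null(vel)) vel <- phase_to_velocity(series)
  vsd <- apply(vel$velocity, c(2L, 3L), stats::sd)
  mbar <- apply(series$magnitude, c(2L, 3L), mean)
  vsd <= stats::quantile(vsd, 0.25) & mbar >= stats::median(mbar)
}

#' Flow through a contour at its cardiac phase
#'
#' Sums velocity over interior pixel centers times the pixel area:
#' `sum v_i (cm/s) * dA (cm^2)` in ml/s.
#'
#' @param vel a `pc_velocity`.
#' @param c a [pc_contour()] (its `phase_index` selects the frame).
#' @param pixel_spacing `(dy, dx)` in mm.
#' @return Flow in ml/s.
#' @export
flow_per_phase <- function(vel, c, pixel_spacing) {
  stopifnot(inherits(vel, "pc_velocity"))
  d <- dim(vel$velocity)
  px <- interior_pixels(c, dim = d[2:3])
  if (!nrow(px)) stop("contour contains no pixel centers")
  v <- vel$velocity[cbind(c$phase_index + 1L, px[, 2L] + 1L, px[, 1L] + 1L)]
  area_cm2 <- (pixel_spacing[1L] / 10) * (pixel_spacing[2L] / 10)
  sum(v) * area_cm2
}

#' Per-phase flow curve for a segmentation
#'
#' @param vel a `pc_velocity`.
#' @param seg a [pc_segmentation()].
#' @param pixel_spacing `(dy, dx)` in mm.
#' @return Numeric vector of length T, ml/s.
#' @export
flow_curve <- function(vel, seg, pixel_spacing) {
  stopifnot(inherits(seg, "pc_segmentation"))
  vapply(seg$contours, flow_per_phase, numeric(1L),
         vel = vel, pixel_spacing = pixel_spacing)
}

#' Net flow volume over the cardiac cycle
#'
#' The time-sum of the flow curve: `sum(flows) * dt`, with `dt` in seconds.
#'
#' @param flows per-phase flow, ml/s.
#' @param temporal_resolution ms per phase.
#' @return Net volume in ml.
#' @export
net_flow_volume <- function(flows, temporal_resolution) {
  sum(flows) * temporal_resolution / 1000
}

#' Cardiac index
#'
#' Net aortic flow volume times heart rate, divided by body surface area.
#'
#' @param net_volume aortic net flow volume, ml.
#' @param rr_interval cardiac cycle duration, ms.
#' @param bsa body surface area, m^2.
#' @return Cardiac index in l/min/m^2.
#' @export
cardiac_index <- function(net_volume, rr_interval, bsa) {
  if (bsa <= 0) stop("bsa must be positive")
  net_volume * (60000 / rr_interval) / bsa / 1000
}

#' Pulmonary-to-systemic flow ratio (Qp/Qs)
#'
#' @param pulm_volume pulmonary net flow volume, ml.
#' @param aorta_volume aortic net flow volume, ml (> 0).
#' @return Dimensionless ratio; ~1 in the absence of a shunt.
#' @export
qp_qs <- function(pulm_volume, aorta_volume) {
  if (aorta_volume <= 0) stop("aorta_volume must be positive")
  pulm_volume / aorta_volume
}

#' Quantify flow for a segmented series
#'
#' Convenience wrapper: converts phase to velocity, optionally applies linear
#' background correction with the default static-tissue mask, and assembles
#' the per-phase flow curve, net volume, heart rate and (given `bsa`) cardiac
#' index.
#'
#' @param series a [pc_series()].
#' @param seg a [pc_segmentation()].
#' @param bsa optional body surface area, m^2.
#' @param correct_background apply [linear_background_correction()]?
#' @param static_mask optional logical mask overriding [static_tissue_mask()].
#' @return A `pc_flow`: list with `flow_per_phase` (ml/s), `net_volume` (ml),
#'   `heart_rate` (bpm), `cardiac_index` (or `NA`), `corrected`.
#' @export
quantify_flow <- function(series, seg, bsa = NULL, correct_background = TRUE,
                          static_mask = NULL) {
  vel <- phase_to_velocity(series)
  if (correct_background) {
    if (is.null(static_mask)) static_mask <- static_tissue_mask(series, vel)
    vel <- linear_background_correction(vel, static_mask)
  }
  flows <- flow_curve(vel, seg, series$pixel_spacing)
  nv <- net_flow_volume(flows, series$temporal_resolution)
  structure(
    list(
      flow_per_phase = flows,
      net_volume = nv,
      heart_rate = 60000 / series$rr_interval,
      cardiac_index = if (is.null(bsa)) NA_real_ else
        cardiac_index(nv, series$rr_interval, bsa),
      corrected = vel$corrected
    ),
    class = "pc_flow"
  )
}

#' @export
print.pc_flow <- function(x, ...) {
  cat(sprintf(
    "<pc_flow> net volume %.1f ml over %d phases, HR %.0f bpm%s\n",
    x$net_volume, length(x$flow_per_phase), x$heart_rate,
    if (is.na(x$cardiac_index)) "" else
      sprintf(", CI %.2f l/min/m^2", x$cardiac_index)
  ))
  invisible(x)
}
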