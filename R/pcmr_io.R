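#' Time-resolved PC-MR image series
#'
#' Container for a paired magnitude / velocity-encoded phase acquisition of a
#' single 2D slice over the cardiac cycle, together with the acquisition
#' metadata needed for flow quantification.
#'
#' @param magnitude numeric T x H x W array, arbitrary units >= 0.
#' @param phase numeric T x H x W array of phase values in radians, in
#'   `[-pi, pi)`.
#' @param pixel_spacing length-2 numeric `(dy, dx)` in mm per pixel.
#' @param temporal_resolution time per cardiac phase, ms.
#' @param venc velocity-encoding limit, cm/s; phase `+/-pi` maps to `+/-venc`.
#' @param rr_interval cardiac cycle duration, ms.
#' @param vessel_label one of `"aorta"`, `"pulmonary"`, `"other"`.
#' @return An object of class `pc_series`.
#' @export
pc_series <- function(magnitude, phase, pixel_spacing, temporal_resolution,
                      venc, rr_interval, vessel_label = "other") {
  if (!identical(dim(magnitude), dim(phase))) {
    stop("magnitude and phase stacks must have identical dimensions")
  }
  d <- dim(magnitude)
  if (length(d) != 3L || d[1L] < 2L) stop("need a T x H x W stack with T >= 2")
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (any(pixel_spacing <= 0)) stop("pixel_spacing must be positive")
  if (venc <= 0) stop("venc must be positive")
  if (temporal_resolution <= 0 || rr_interval <= 0) {
    stop("temporal_resolution and rr_interval must be positive")
  }
  # 10% slack accommodates prospective gating (acquisition shorter than RR)
  if (d[1L] * temporal_resolution > rr_interval * 1.10) {
    stop("T x temporal_resolution exceeds the RR interval by more than 10%")
  }
  if (min(phase) < -pi - 1e-9 || max(phase) >= pi + 1e-9) {
    stop("phase values must lie in [-pi, pi) radians")
  }
  vessel_label <- match.arg(vessel_label, c("aorta", "pulmonary", "other"))
  structure(
    list(
      magnitude = magnitude, phase = phase,
      pixel_spacing = pixel_spacing,
      temporal_resolution = as.numeric(temporal_resolution),
      venc = as.numeric(venc), rr_interval = as.numeric(rr_interval),
      vessel_label = vessel_label
    ),
    class = "pc_series"
  )
}

#' @export
print.pc_series <- function(x, ...) {
  d <- dim(x$magnitude)
  cat(sprintf(
    "<pc_series> %s, %d phases of %d x %d px, dt %.1f ms, RR %.0f ms, VENC %.0f cm/s\n",
    x$vessel_label, d[1L], d[2L], d[3L], x$temporal_resolution,
    x$rr_interval, x$venc
  ))
  invisible(x)
}

n_phases <- function(series) dim(series$magnitude)[1L]

#' Convert encoded phase to through-plane velocity
#'
#' Applies the standard linear PC-MR velocity encoding: a phase of `+/-pi`
#' radians corresponds to `+/-VENC` cm/s, so `v = phase / pi * venc`.
#' Velocities are taken at face value; no phase unwrapping is attempted
#' (acquisitions are assumed to use a VENC above the peak velocity).
#'
#' @param series a [pc_series()].
#' @return A `pc_velocity` object: list with `velocity` (T x H x W array,
#'   cm/s) and `corrected` (logical, `FALSE` until background correction).
#' @export
phase_to_velocity <- function(series) {
  stopifnot(inherits(series, "pc_series"))
  structure(
    list(velocity = series$phase / pi * series$venc, corrected = FALSE),
    class = "pc_velocity"
  )
}

# --- array container -------------------------------------------------------
# A series is stored as a directory:
#   meta.json      acquisition metadata + array dims + byte order
#   magnitude.bin  float64, little-endian, T*H*W values in R array order
#   phase.bin      float64, little-endian, same layout

#' Write a PC-MR series to the pcflow array container
#'
#' The container is a directory holding `meta.json` (metadata and array
#' dimensions) plus raw little-endian float64 dumps of the magnitude and phase
#' stacks. Round-trips through [read_series()] are bit-exact.
#'
#' @param series a [pc_series()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "pc_series"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    schema = "pcflow-series-1",
    dim = dim(series$magnitude),
    byte_order = "little",
    dtype = "float64",
    pixel_spacing = series$pixel_spacing,
    temporal_resolution = series$temporal_resolution,
    venc = series$venc,
    rr_interval = series$rr_interval,
    vessel_label = series$vessel_label
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in c("magnitude", "phase")) {
    con <- file(file.path(path, paste0(nm, ".bin")), "wb")
    writeBin(as.vector(series[[nm]]), con, size = 8L, endian = "little")
    close(con)
  }
  invisible(path)
}

#' Read a PC-MR series
#'
#' @param path container directory written by [write_series()].
#' @param format only `"array-container"` is supported.
#' @return A [pc_series()].
#' @export
read_series <- function(path, format = c("array-container", "dicom")) {
  format <- match.arg(format)
  if (format == "dicom") {
    stop("DICOM reading is not supported; export to the array container ",
         "(see write_series) instead")
  }
  if (!dir.exists(path)) stop("series container not found: ", path)
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("meta.json not found in ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("dim", "pixel_spacing", "temporal_resolution", "venc",
                  "rr_interval")) {
    if (is.null(meta[[field]])) stop("series metadata missing field: ", field)
  }
  d <- as.integer(meta$dim)
  n <- prod(d)
  arrays <- lapply(c("magnitude", "phase"), function(nm) {
    f <- file.path(path, paste0(nm, ".bin"))
    if (!file.exists(f)) stop(nm, " series not found in ", path)
    con <- file(f, "rb")
    on.exit(close(con))
    v <- readBin(con, "double", n = n, size = 8L, endian = "little")
    if (length(v) != n) stop(nm, ".bin truncated: expected ", n, " values")
    array(v, dim = d)
  })
  pc_series(arrays[[1L]], arrays[[2L]],
            pixel_spacing = meta$pixel_spacing,
            temporal_resolution = meta$temporal_resolution,
            venc = meta$venc, rr_interval = meta$rr_interval,
            vessel_label = if (is.null(meta$vessel_label)) "other" else meta$vessel_label)
}

# --- segmentation result ----------------------------------------------------

#' Time-resolved segmentation result
#'
#' One contour per cardiac phase plus the provenance of how the series was
#' processed: the order phases were segmented in, the rigid shift applied when
#' initializing each phase, and the high-velocity phase set from clustering.
#'
#' @param contours list of [pc_contour()], one per phase `0..T-1`, in phase
#'   order.
#' @param processing_order integer permutation of `0..T-1` (0-based).
#' @param shifts T x 2 numeric matrix of applied (dx, dy) shifts in pixels.
#' @param high_velocity_phases integer vector of 0-based phase indices.
#' @param seed_phase 0-based phase index of the manual delineation.
#' @return An object of class `pc_segmentation`.
#' @export
pc_segmentation <- function(contours, processing_order = NULL, shifts = NULL,
                            high_velocity_phases = integer(0),
                            seed_phase = 0L) {
  T_ <- length(contours)
  if (!T_) stop("need at least one contour")
  ok <- vapply(contours, inherits, logical(1L), what = "pc_contour")
  if (!all(ok)) stop("contours must all be pc_contour objects")
  phases <- vapply(contours, function(c) c$phase_index, integer(1L))
  if (!identical(phases, seq_len(T_) - 1L)) {
    stop("contours must carry phase_index 0..T-1 in order")
  }
  if (is.null(processing_order)) processing_order <- seq_len(T_) - 1L
  if (!identical(sort(as.integer(processing_order)), seq_len(T_) - 1L)) {
    stop("processing_order must be a permutation of 0..T-1")
  }
  if (is.null(shifts)) shifts <- matrix(0, T_, 2L)
  shifts <- matrix(as.numeric(shifts), T_, 2L)
  structure(
    list(
      contours = contours,
      processing_order = as.integer(processing_order),
      shifts = shifts,
      high_velocity_phases = as.integer(high_velocity_phases),
      seed_phase = as.integer(seed_phase)
    ),
    class = "pc_segmentation"
  )
}

#' @export
print.pc_segmentation <- function(x, ...) {
  cat(sprintf(
    "<pc_segmentation> %d phases, seed phase %d, %d high-velocity phases\n",
    length(x$contours), x$seed_phase, length(x$high_velocity_phases)
  ))
  invisible(x)
}

#' Write / read segmentation contours as JSON
#'
#' Schema `pcflow-contours-1`: a metadata block (seed phase, processing order,
#' shifts, high-velocity set) and one `{phase_index, points}` record per
#' cardiac phase. Round-trips exactly (point coordinates are serialized at
#' full precision).
#'
#' @param seg a [pc_segmentation()].
#' @param path output JSON file.
#' @return `path` invisibly for `write_contours`; a [pc_segmentation()] for
#'   `read_contours`.
#' @export
write_contours <- function(seg, path) {
  stopifnot(inherits(seg, "pc_segmentation"))
  obj <- list(
    schema = "pcflow-contours-1",
    seed_phase = seg$seed_phase,
    processing_order = seg$processing_order,
    high_velocity_phases = seg$high_velocity_phases,
    shifts = unname(apply(seg$shifts, 1L, as.list, simplify = FALSE)),
    contours = lapply(seg$contours, function(c) {
      list(phase_index = c$phase_index,
           points = unname(apply(c$points, 1L, as.list, simplify = FALSE)))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) stop("contour file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$contours) || !length(obj$contours)) {
    stop("contour file has no contours block")
  }
  contours <- lapply(obj$contours, function(rec) {
    idx <- rec$phase_index
    pts <- rec$points
    if (is.null(idx) || is.null(pts) || length(pts) < 3L) {
      stop("invalid contour record at phase index ",
           if (is.null(idx)) "<missing>" else idx,
           ": need a phase_index and at least 3 points")
    }
    pm <- do.call(rbind, lapply(pts, function(p) as.numeric(unlist(p))))
    if (ncol(pm) != 2L) stop("invalid points at phase index ", idx)
    pc_contour(pm, phase_index = as.integer(idx))
  })
  shifts <- if (!is.null(obj$shifts)) {
    do.call(rbind, lapply(obj$shifts, function(s) as.numeric(unlist(s))))
  } else NULL
  pc_segmentation(
    contours,
    processing_order = if (!is.null(obj$processing_order))
      as.integer(unlist(obj$processing_order)) else NULL,
    shifts = shifts,
    high_velocity_phases = as.integer(unlist(obj$high_velocity_phases)),
    seed_phase = if (is.null(obj$seed_phase)) 0L else as.integer(obj$seed_phase)
  )
}
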