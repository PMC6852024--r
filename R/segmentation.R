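# The semi-automatic segmentation pipeline: rigid motion tracking,
# velocity-based phase ordering, edge-guided active contour, PCA
# shape-constrained reconstruction, and final diameter rescaling.

#' Algorithm parameters
#'
#' Tunable parameters of the segmentation pipeline. Defaults are calibrated on
#' the synthetic pulsatile phantom via [optimize_parameters()]-style sweeps;
#' all are exposed for re-optimization on other data.
#'
#' @param snake_iterations explicit-Euler iterations of the active contour.
#' @param edge_weight weight of the (unit-normalized) image edge force.
#' @param tension_weight weight of the first-order (tension) internal force.
#' @param rigidity_weight weight of the second-order (rigidity) internal force.
#' @param gradient_sigma Gaussian scale (pixels) of the edge map.
#' @param scale_factor final multiplicative diameter rescale, in `[0.8, 1.2]`;
#'   compensates the inward bias of edge detection on blurred lumen borders.
#' @param search_radius motion-tracking search radius, pixels.
#' @param curvature_mode `"pca"` for the shape-model-constrained method,
#'   `"curvature-force"` for the comparison variant that relies on the snake's
#'   internal curvature forces only (no PCA reconstruction step).
#' @param step_size Euler step of the snake update.
#' @param n_snake_points contour vertices maintained during deformation.
#' @param reconstruct_every_k_iterations if > 0, interleave a shape-constrained
#'   reconstruction into the snake loop every k iterations instead of only
#'   once after deformation.
#' @return A list of class `pc_params`.
#' @export
algorithm_params <- function(snake_iterations = 100L,
                             edge_weight = 1.0,
                             tension_weight = 0.05,
                             rigidity_weight = 0.01,
                             gradient_sigma = 2.0,
                             scale_factor = 1.02,
                             search_radius = 10L,
                             curvature_mode = c("pca", "curvature-force"),
                             step_size = 0.2,
                             n_snake_points = 48L,
                             reconstruct_every_k_iterations = 0L) {
  curvature_mode <- match.arg(curvature_mode)
  if (scale_factor < 0.8 || scale_factor > 1.2) {
    stop("scale_factor must lie in [0.8, 1.2]")
  }
  if (edge_weight < 0 || tension_weight < 0 || rigidity_weight < 0) {
    stop("force weights must be non-negative")
  }
  structure(
    list(
      snake_iterations = as.integer(snake_iterations),
      edge_weight = edge_weight, tension_weight = tension_weight,
      rigidity_weight = rigidity_weight, gradient_sigma = gradient_sigma,
      scale_factor = scale_factor, search_radius = as.integer(search_radius),
      curvature_mode = curvature_mode, step_size = step_size,
      n_snake_points = as.integer(n_snake_points),
      reconstruct_every_k_iterations = as.integer(reconstruct_every_k_iterations)
    ),
    class = "pc_params"
  )
}

#' Rigid motion between two magnitude frames
#'
#' Finds the integer-pixel shift of the vessel neighborhood between two
#' adjacent cardiac phases by exhaustive normalized cross-correlation. The
#' template is the bounding box of `roi` dilated by 4 pixels in `mag_a`,
#' matched against `mag_b` over all shifts in
#' `[-search_radius, search_radius]^2`. Both frames are Gaussian-smoothed
#' (`smooth_sigma`) before matching, which suppresses per-pixel noise without
#' biasing the correlation peak (an integer translation commutes with the
#' smoothing). Ties (within 1e-12 of the best score) are broken by smallest
#' `|dx| + |dy|`, then lexicographically by `(dx, dy)`, so featureless images
#' yield `(0, 0)`.
#'
#' @param mag_a,mag_b H x W magnitude images.
#' @param roi a [pc_contour()] marking the vessel in `mag_a`.
#' @param search_radius maximum shift magnitude per axis, pixels.
#' @param smooth_sigma Gaussian pre-smoothing scale, pixels; 0 disables.
#' @return Integer `(dx, dy)`: the content of `mag_a` at `(x, y)` appears in
#'   `mag_b` at `(x + dx, y + dy)`.
#' @export
track_rigid_motion <- function(mag_a, mag_b, roi, search_radius = 10L,
                               smooth_sigma = 1.5) {
  stopifnot(identical(dim(mag_a), dim(mag_b)), inherits(roi, "pc_contour"))
  H <- nrow(mag_a); W <- ncol(mag_a)
  if (smooth_sigma > 0) {
    mag_a <- EBImage::gblur(mag_a, sigma = smooth_sigma)
    mag_b <- EBImage::gblur(mag_b, sigma = smooth_sigma)
  }
  r <- as.integer(search_radius)
  x0 <- floor(min(roi$points[, 1L])) - 4L; x1 <- ceiling(max(roi$points[, 1L])) + 4L
  y0 <- floor(min(roi$points[, 2L])) - 4L; y1 <- ceiling(max(roi$points[, 2L])) + 4L
  if (x0 - r < 0L || y0 - r < 0L || x1 + r > W - 1L || y1 + r > H - 1L) {
    stop("motion-tracking patch leaves the image under the maximal shift")
  }
  A <- mag_a[(y0:y1) + 1L, (x0:x1) + 1L]
  a <- as.vector(A) - mean(A)
  sa <- sqrt(sum(a^2))
  shifts <- expand.grid(dx = -r:r, dy = -r:r)
  score <- vapply(seq_len(nrow(shifts)), function(i) {
    dx <- shifts$dx[i]; dy <- shifts$dy[i]
    B <- mag_b[(y0 + dy):(y1 + dy) + 1L, (x0 + dx):(x1 + dx) + 1L]
    b <- as.vector(B) - mean(B)
    sb <- sqrt(sum(b^2))
    if (sa < 1e-12 || sb < 1e-12) return(0)
    sum(a * b) / (sa * sb)
  }, numeric(1L))
  best <- which(score >= max(score) - 1e-12)
  ord <- order(abs(shifts$dx[best]) + abs(shifts$dy[best]),
               shifts$dx[best], shifts$dy[best])
  i <- best[ord[1L]]
  c(dx = shifts$dx[i], dy = shifts$dy[i])
}

#' Spatial median velocity inside a contour
#'
#' @param vel a `pc_velocity` from [phase_to_velocity()].
#' @param phase_index 0-based cardiac phase.
#' @param c a [pc_contour()].
#' @return Median velocity (cm/s) over interior pixel centers.
#' @export
median_velocity_inside <- function(vel, phase_index, c) {
  stopifnot(inherits(vel, "pc_velocity"))
  d <- dim(vel$velocity)
  px <- interior_pixels(c, dim = d[2:3])
  if (!nrow(px)) stop("contour contains no pixel centers at phase ", phase_index)
  v <- vel$velocity[cbind(phase_index + 1L, px[, 2L] + 1L, px[, 1L] + 1L)]
  stats::median(v)
}

#' Split cardiac phases into high- and low-velocity classes
#'
#' Deterministic one-dimensional 2-means on the absolute median velocities.
#' In one dimension the optimal 2-means partition is a threshold in sorted
#' order, so the globally optimal split (minimum within-class sum of squares)
#' is found exactly by scanning all sorted splits; no iterative refinement or
#' random initialization is involved. If all medians are identical the split
#' is degenerate and every phase is reported as high-velocity (with a
#' warning).
#'
#' @param medians numeric vector of per-phase median velocities (cm/s), length
#'   T >= 2.
#' @return List with `high` and `low`: sorted 0-based phase index vectors.
#' @export
cluster_time_phases <- function(medians) {
  T_ <- length(medians)
  stopifnot(T_ >= 2L)
  x <- abs(medians)
  if (diff(range(x)) < 1e-12) {
    warning("all median velocities identical; degenerate clustering, ",
            "treating every phase as high-velocity")
    return(list(high = seq_len(T_) - 1L, low = integer(0)))
  }
  ord <- order(x)
  xs <- x[ord]
  sse <- function(v) if (length(v) < 2L) 0 else sum((v - mean(v))^2)
  scores <- vapply(seq_len(T_ - 1L), function(k) {
    sse(xs[seq_len(k)]) + sse(xs[(k + 1L):T_])
  }, numeric(1L))
  k <- which.min(scores)
  low <- sort(ord[seq_len(k)] - 1L)
  high <- sort(ord[(k + 1L):T_] - 1L)
  list(high = high, low = low)
}

#' Processing order of cardiac phases
#'
#' The segmentation starts at the seed phase if it belongs to the
#' high-velocity class, otherwise at the phase with the largest absolute
#' median velocity. The "high-velocity interval" is the contiguous run of
#' high-class phases containing the start. Phases are processed start-first,
#' forward to the end of the interval, backward to its beginning, then forward
#' from the interval to T-1, and finally backward from the interval to 0 —
#' so every phase is initialized from an already-processed temporal neighbor.
#'
#' @param high_set 0-based indices of high-velocity phases (non-empty).
#' @param seed_phase 0-based seed phase.
#' @param T_ total number of phases.
#' @param medians per-phase median velocities; required when `seed_phase` is
#'   not in `high_set`.
#' @return Integer vector: a permutation of `0..T-1`.
#' @export
processing_order <- function(high_set, seed_phase, T_, medians = NULL) {
  stopifnot(length(high_set) >= 1L)
  high <- sort(as.integer(high_set))
  start <- if (seed_phase %in% high) {
    as.integer(seed_phase)
  } else {
    if (is.null(medians)) {
      stop("seed phase is not in the high-velocity class; medians needed to pick the start")
    }
    which.max(abs(medians)) - 1L
  }
  # contiguous run of high-class phases containing the start
  lo <- start; while ((lo - 1L) %in% high) lo <- lo - 1L
  hi <- start; while ((hi + 1L) %in% high) hi <- hi + 1L
  order <- c(
    start:hi,
    if (lo <= start - 1L) (start - 1L):lo,
    if (hi + 1L <= T_ - 1L) (hi + 1L):(T_ - 1L),
    if (lo - 1L >= 0L) (lo - 1L):0L
  )
  as.integer(order)
}

# Gaussian edge-force field of a magnitude image: the gradient of the
# (max-normalized) gradient magnitude of the sigma-smoothed image. Unit
# normalization makes edge_weight contrast-invariant across frames.
edge_force_field <- function(mag, sigma) {
  S <- EBImage::gblur(mag, sigma = sigma)
  gx <- central_diff_x(S); gy <- central_diff_y(S)
  M <- sqrt(gx^2 + gy^2)
  mx <- max(M)
  if (mx > 0) M <- M / mx
  list(fx = central_diff_x(M), fy = central_diff_y(M))
}

central_diff_x <- function(m) {
  W <- ncol(m)
  d <- (m[, c(2:W, W)] - m[, c(1L, 1:(W - 1L))]) / 2
  d[, 1L] <- m[, 2L] - m[, 1L]; d[, W] <- m[, W] - m[, W - 1L]
  d
}

central_diff_y <- function(m) {
  H <- nrow(m)
  d <- (m[c(2:H, H), ] - m[c(1L, 1:(H - 1L)), ]) / 2
  d[1L, ] <- m[2L, ] - m[1L, ]; d[H, ] <- m[H, ] - m[H - 1L, ]
  d
}

#' Edge-guided active contour deformation
#'
#' Classic explicit snake on one magnitude frame: vertices move under the
#' external force (gradient of the Gaussian edge map, bilinearly interpolated)
#' plus internal tension (discrete Laplacian, curve-shortening) and rigidity
#' (negative fourth difference) forces. After every Euler step the contour is
#' resampled to `n_snake_points` uniform arc-length vertices.
#'
#' @param c a [pc_contour()] inside the image.
#' @param mag H x W magnitude image.
#' @param params an [algorithm_params()].
#' @param force optional precomputed [edge force field][deform_active_contour]
#'   (list with `fx`, `fy`) to avoid recomputing it per call.
#' @return Deformed [pc_contour()] with `params$n_snake_points` vertices.
#' @export
deform_active_contour <- function(c, mag, params, force = NULL) {
  stopifnot(inherits(c, "pc_contour"))
  H <- nrow(mag); W <- ncol(mag)
  if (is.null(force)) force <- edge_force_field(mag, params$gradient_sigma)
  n <- params$n_snake_points
  P <- resample_polygon(c$points, n)
  ip <- c(n, 1:(n - 1L)); ipp <- c(n - 1L, n, 1:(n - 2L))
  im <- c(2:n, 1L); imm <- c(3:n, 1L, 2L)
  for (iter in seq_len(params$snake_iterations)) {
    fx <- bilinear(force$fx, P[, 1L], P[, 2L])
    fy <- bilinear(force$fy, P[, 1L], P[, 2L])
    lap <- P[ip, ] - 2 * P + P[im, ]
    fourth <- P[ipp, ] - 4 * P[ip, ] + 6 * P - 4 * P[im, ] + P[imm, ]
    upd <- params$edge_weight * cbind(fx, fy) +
      params$tension_weight * lap - params$rigidity_weight * fourth
    P <- P + params$step_size * upd
    P[, 1L] <- pmin(pmax(P[, 1L], 0), W - 1L)
    P[, 2L] <- pmin(pmax(P[, 2L], 0), H - 1L)
    P <- resample_polygon(P, n)
  }
  out <- pc_contour(P, phase_index = c$phase_index, check = FALSE)
  if (nrow(interior_pixels(out, dim = c(H, W))) < 3L) stop("contour collapse")
  out
}

#' Rescale a contour about its centroid
#'
#' Moves every vertex radially about the area centroid by `scale_factor`; the
#' centroid is preserved and the area scales by `scale_factor^2`.
#'
#' @param c a [pc_contour()].
#' @param scale_factor positive multiplicative factor on the diameter.
#' @return Rescaled [pc_contour()].
#' @export
rescale_contour <- function(c, scale_factor) {
  stopifnot(scale_factor > 0)
  ctr <- contour_centroid(c)
  pts <- sweep(sweep(c$points, 2L, ctr) * scale_factor, 2L, ctr, "+")
  pc_contour(pts, phase_index = c$phase_index, check = FALSE)
}

# deform + (optionally interleaved) shape-constrained reconstruction of one
# frame
process_frame <- function(init, mag, model, params, force = NULL) {
  k <- params$reconstruct_every_k_iterations
  use_pca <- params$curvature_mode == "pca"
  if (!use_pca || k <= 0L || k >= params$snake_iterations) {
    out <- deform_active_contour(init, mag, params, force = force)
    if (use_pca) out <- reconstruct_shape(out, model)
    return(out)
  }
  remaining <- params$snake_iterations
  cur <- init
  chunk_params <- params
  while (remaining > 0L) {
    chunk_params$snake_iterations <- min(k, remaining)
    cur <- deform_active_contour(cur, mag, chunk_params, force = force)
    cur <- reconstruct_shape(cur, model)
    remaining <- remaining - min(k, remaining)
  }
  cur
}

shift_contour <- function(c, dxy) {
  pc_contour(sweep(c$points, 2L, as.numeric(dxy), "+"),
             phase_index = c$phase_index, check = FALSE)
}

#' Segment a PC-MR series from one manual delineation
#'
#' The full semi-automatic pipeline: (1) rigid motion tracking between
#' adjacent magnitude frames around the (propagated) seed contour; (2) spatial
#' median velocity inside the motion-tracked seed per phase; (3) 2-means
#' split into high/low velocity classes and derivation of the processing
#' order; (4) per phase in that order, initialization from the previously
#' processed temporal neighbor shifted by the tracked motion, active contour
#' deformation on the magnitude image, and (for `curvature_mode = "pca"`)
#' shape-constrained reconstruction; (5) rescaling of every contour by the
#' fixed `scale_factor`. When the seed phase is the starting phase its manual
#' contour is trusted as-is (rescaled only); otherwise the seed phase is
#' re-processed like any other frame, initialized from the manual contour.
#'
#' The pipeline is fully deterministic: identical inputs give bit-identical
#' results.
#'
#' @param series a [pc_series()].
#' @param seed a [pc_contour()] with `phase_index` set to the delineated phase.
#' @param model a `pc_shape_model` (matching `series$vessel_label`); may be
#'   `NULL` when `curvature_mode = "curvature-force"`.
#' @param params an [algorithm_params()].
#' @return A [pc_segmentation()] with full provenance.
#' @export
segment_series <- function(series, seed, model = NULL,
                           params = algorithm_params()) {
  stopifnot(inherits(series, "pc_series"), inherits(seed, "pc_contour"))
  T_ <- n_phases(series)
  seed_phase <- seed$phase_index
  if (seed_phase < 0L || seed_phase >= T_) stop("seed phase out of range")
  if (params$curvature_mode == "pca") {
    if (is.null(model)) stop("curvature_mode 'pca' needs a shape model")
    if (!identical(model$vessel_label, series$vessel_label)) {
      stop("shape model vessel label (", model$vessel_label,
           ") does not match the series (", series$vessel_label, ")")
    }
  }
  mag <- function(t) series$magnitude[t + 1L, , ]

  # step 1: pairwise shifts t -> t+1, tracked around the propagated seed
  pair_shift <- matrix(0, max(T_ - 1L, 1L), 2L)
  tryCatch({
    cur <- seed
    if (seed_phase < T_ - 1L) for (t in seed_phase:(T_ - 2L)) {
      s <- track_rigid_motion(mag(t), mag(t + 1L), cur, params$search_radius)
      pair_shift[t + 1L, ] <- s
      cur <- shift_contour(cur, s)
    }
    cur <- seed
    if (seed_phase > 0L) for (t in seed_phase:1L) {
      s <- track_rigid_motion(mag(t), mag(t - 1L), cur, params$search_radius)
      pair_shift[t, ] <- -s   # stored as the t-1 -> t shift
      cur <- shift_contour(cur, s)
    }
  }, error = function(e) stop("motion tracking failed: ", conditionMessage(e)))

  # cumulative position of the seed contour at every phase
  cum_shift <- matrix(0, T_, 2L)
  if (seed_phase < T_ - 1L) for (t in (seed_phase + 1L):T_ - 1L) {
    if (t > seed_phase) cum_shift[t + 1L, ] <- cum_shift[t, ] + pair_shift[t, ]
  }
  if (seed_phase > 0L) for (t in seed_phase:1L) {
    cum_shift[t, ] <- cum_shift[t + 1L, ] - pair_shift[t, ]
  }
  tracked_seed <- lapply(0:(T_ - 1L), function(t) {
    ct <- shift_contour(seed, cum_shift[t + 1L, ])
    ct$phase_index <- as.integer(t)
    ct
  })

  # step 2: median velocities inside the motion-tracked delineation
  vel <- phase_to_velocity(series)
  medians <- vapply(0:(T_ - 1L), function(t) {
    median_velocity_inside(vel, t, tracked_seed[[t + 1L]])
  }, numeric(1L))

  # step 3: clustering and processing order
  classes <- cluster_time_phases(medians)
  order <- processing_order(classes$high, seed_phase, T_, medians)
  start <- order[1L]

  # step 4: per-frame deformation (+ reconstruction)
  results <- vector("list", T_)
  applied_shift <- matrix(0, T_, 2L)
  processed <- rep(FALSE, T_)
  force_cache <- vector("list", T_)
  frame_force <- function(t) {
    if (is.null(force_cache[[t + 1L]])) {
      force_cache[[t + 1L]] <<- edge_force_field(mag(t), params$gradient_sigma)
    }
    force_cache[[t + 1L]]
  }
  for (p in order) {
    res <- tryCatch({
      if (p == start) {
        if (p == seed_phase) {
          seed   # trust the manual delineation at the starting phase
        } else {
          init <- tracked_seed[[p + 1L]]
          applied_shift[p + 1L, ] <- cum_shift[p + 1L, ]
          process_frame(init, mag(p), model, params, force = frame_force(p))
        }
      } else if (p == seed_phase) {
        process_frame(seed, mag(p), model, params, force = frame_force(p))
      } else {
        q <- if (p >= 1L && processed[p]) p - 1L else p + 1L
        s <- if (q == p - 1L) pair_shift[p, ] else -pair_shift[p + 1L, ]
        applied_shift[p + 1L, ] <- s
        init <- shift_contour(results[[q + 1L]], s)
        init$phase_index <- as.integer(p)
        process_frame(init, mag(p), model, params, force = frame_force(p))
      }
    }, error = function(e) {
      stop("segmentation failed at phase ", p, ": ", conditionMessage(e))
    })
    res$phase_index <- as.integer(p)
    results[[p + 1L]] <- res
    processed[p + 1L] <- TRUE
  }

  # step 5: fixed diameter rescale
  results <- lapply(results, rescale_contour, scale_factor = params$scale_factor)

  pc_segmentation(
    results,
    processing_order = order,
    shifts = applied_shift,
    high_velocity_phases = classes$high,
    seed_phase = seed_phase
  )
}
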