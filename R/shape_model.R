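# Radial shape parameterization and the PCA statistical shape model.
#
# A contour is described by the distances from a reference center to the
# boundary along n equiangular rays, normalized by their mean. Translation
# (center) and isotropic scale (mean radius) are removed before PCA and
# restored at reconstruction, so the model constrains shape only.
#
# The reference center is the radial-harmonic center: the point about which
# the sampled radial profile has zero first circular harmonic
# (sum_i r_i * (cos th_i, sin th_i) = 0). Deviations from the model mean then
# live in a linear subspace with zero mean and zero first harmonic, which
# makes PCA reconstruction preserve the center and the mean radius exactly
# and makes it idempotent.

shape_angles <- function(n_points) 2 * pi * (seq_len(n_points) - 1L) / n_points

# distance from `center` to the polygon boundary along each angle.
# Errors if a ray crosses the boundary more than once (non-star-shaped
# contour) or not at all (center outside).
ray_radii <- function(points, center, angles) {
  n <- nrow(points)
  p1 <- points
  p2 <- points[c(2:n, 1L), , drop = FALSE]
  e <- p2 - p1
  w <- cbind(p1[, 1L] - center[1L], p1[, 2L] - center[2L])
  vapply(angles, function(th) {
    d <- c(cos(th), sin(th))
    denom <- d[1L] * e[, 2L] - d[2L] * e[, 1L]
    ok <- abs(denom) > 1e-12
    t_ <- (w[, 1L] * e[, 2L] - w[, 2L] * e[, 1L]) / denom
    s_ <- (w[, 1L] * d[2L] - w[, 2L] * d[1L]) / denom
    # endpoint tolerance is generous on both sides: a ray grazing a vertex
    # registers on both adjacent edges at the same distance and is collapsed
    # by the dedupe below
    hit <- ok & s_ >= -1e-6 & s_ < 1 + 1e-6 & t_ > 1e-9
    tt <- sort(t_[hit])
    if (length(tt) > 1L) tt <- tt[c(TRUE, diff(tt) > 1e-6 * max(tt))]
    if (length(tt) == 0L) {
      stop(sprintf("ray at %.1f deg does not hit the boundary (center outside contour?)",
                   th * 180 / pi))
    }
    if (length(tt) > 1L) {
      stop(sprintf("contour is not star-shaped: ray at %.1f deg crosses the boundary %d times",
                   th * 180 / pi, length(tt)))
    }
    tt
  }, numeric(1L))
}

# radial-harmonic center by damped fixed-point iteration from the area
# centroid; damping 1 converges geometrically for star-shaped contours
shape_center <- function(points, angles, tol = 1e-12, max_iter = 500L) {
  ctr <- contour_centroid(list(points = points))
  ux <- cos(angles); uy <- sin(angles)
  for (i in seq_len(max_iter)) {
    r <- ray_radii(points, ctr, angles)
    step <- c(mean(r * ux), mean(r * uy))
    ctr <- ctr + step
    if (sqrt(sum(step^2)) < tol) return(ctr)
  }
  stop("shape center iteration did not converge")
}

#' Radial shape parameterization of a contour
#'
#' Samples the boundary distance along `n_points` equiangular rays from the
#' contour's radial-harmonic center and normalizes by the mean radius. The
#' returned shape vector separates pose (center), size (`scale` = mean radius
#' in pixels) and shape (`radii`, mean 1).
#'
#' @param c a [pc_contour()]; must be star-shaped about its center.
#' @param n_points number of rays (model order).
#' @return A `pc_shapevec`: list with `radii` (length `n_points`, mean 1),
#'   `scale`, `centroid` (x, y), `n_points`, `phase_index`.
#' @export
parameterize_contour <- function(c, n_points = 48L) {
  stopifnot(inherits(c, "pc_contour"), n_points >= 3L)
  angles <- shape_angles(n_points)
  ctr <- shape_center(c$points, angles)
  r <- ray_radii(c$points, ctr, angles)
  s <- mean(r)
  structure(
    list(radii = r / s, scale = s, centroid = ctr,
         n_points = as.integer(n_points), phase_index = c$phase_index),
    class = "pc_shapevec"
  )
}

#' Rebuild a contour from a shape vector
#'
#' Inverse of [parameterize_contour()]: places vertices at
#' `centroid + scale * radii_i * (cos th_i, sin th_i)`.
#'
#' @param sv a `pc_shapevec`.
#' @return A [pc_contour()].
#' @export
shape_to_contour <- function(sv) {
  stopifnot(inherits(sv, "pc_shapevec"))
  angles <- shape_angles(sv$n_points)
  pts <- cbind(sv$centroid[1L] + sv$scale * sv$radii * cos(angles),
               sv$centroid[2L] + sv$scale * sv$radii * sin(angles))
  pc_contour(pts, phase_index = sv$phase_index, check = FALSE)
}

#' Fit a PCA shape model from reference delineations
#'
#' Pools the normalized radial shape vectors of every contour of every
#' training segmentation (all cardiac phases of all subjects of one vessel)
#' and extracts principal modes of shape variation by eigendecomposition of
#' the sample covariance. The number of retained modes is the smallest k whose
#' cumulative explained variance reaches `variance_kept`.
#'
#' @param training list of [pc_segmentation()] (or a single one), all from the
#'   same vessel.
#' @param n_points model order (rays per contour).
#' @param variance_kept fraction of total shape variance to retain, in (0, 1].
#' @param clip_sd reconstruction clip bound per mode, in standard deviations.
#' @param vessel_label vessel the model applies to.
#' @return A `pc_shape_model`: list with `mean_shape`, `modes` (n_points x
#'   n_modes_retained, orthonormal columns), `eigenvalues` (all, non-increasing),
#'   `n_modes_retained`, `clip_sd`, `n_points`, `n_training`, `vessel_label`.
#' @export
fit_shape_model <- function(training, n_points = 48L, variance_kept = 0.95,
                            clip_sd = 3, vessel_label = "other") {
  if (inherits(training, "pc_segmentation")) training <- list(training)
  contours <- unlist(lapply(training, function(s) s$contours), recursive = FALSE)
  if (length(contours) < 2L) stop("need at least 2 training contours")
  X <- t(vapply(contours, function(c) parameterize_contour(c, n_points)$radii,
                numeric(n_points)))
  mean_shape <- colMeans(X)
  D <- sweep(X, 2L, mean_shape)
  C <- crossprod(D) / (nrow(X) - 1L)
  ed <- eigen(C, symmetric = TRUE)
  ev <- pmax(ed$values, 0)
  total <- sum(ev)
  k <- if (total < 1e-12) 0L else {
    which(cumsum(ev) / total >= variance_kept - 1e-12)[1L]
  }
  structure(
    list(
      mean_shape = mean_shape,
      modes = ed$vectors[, seq_len(k), drop = FALSE],
      eigenvalues = ev,
      n_modes_retained = as.integer(k),
      clip_sd = as.numeric(clip_sd),
      n_points = as.integer(n_points),
      n_training = nrow(X),
      vessel_label = vessel_label
    ),
    class = "pc_shape_model"
  )
}

#' @export
print.pc_shape_model <- function(x, ...) {
  cat(sprintf(
    "<pc_shape_model> %s: %d rays, %d/%d modes retained (clip %.1f SD), %d training shapes\n",
    x$vessel_label, x$n_points, x$n_modes_retained, length(x$eigenvalues),
    x$clip_sd, x$n_training
  ))
  invisible(x)
}

#' Shape-constrained reconstruction of a contour
#'
#' Projects the contour's normalized shape vector onto the retained PCA modes,
#' clips each mode coefficient to `+/- clip_sd * sqrt(eigenvalue)` (modes with
#' vanishing eigenvalue are forced to zero), and rebuilds the contour about
#' its original center and mean radius. Pose and size are untouched; only the
#' shape is pulled into the span of plausible training shapes.
#'
#' @param c a [pc_contour()].
#' @param model a `pc_shape_model` from [fit_shape_model()].
#' @return A [pc_contour()] with `model$n_points` vertices.
#' @export
reconstruct_shape <- function(c, model) {
  stopifnot(inherits(model, "pc_shape_model"))
  sv <- parameterize_contour(c, model$n_points)
  k <- model$n_modes_retained
  radii <- if (k == 0L) {
    model$mean_shape
  } else {
    b <- drop(crossprod(model$modes, sv$radii - model$mean_shape))
    lam <- model$eigenvalues[seq_len(k)]
    bound <- ifelse(lam < 1e-12, 0, model$clip_sd * sqrt(lam))
    b <- pmin(pmax(b, -bound), bound)
    model$mean_shape + drop(model$modes %*% b)
  }
  if (any(radii <= 0)) stop("shape reconstruction produced non-positive radii")
  sv$radii <- radii
  shape_to_contour(sv)
}

#' Save / load a shape model as JSON
#'
#' @param model a `pc_shape_model`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_shape_model` returns the model.
#' @export
write_shape_model <- function(model, path) {
  stopifnot(inherits(model, "pc_shape_model"))
  obj <- list(
    schema = "pcflow-shape-model-1",
    mean_shape = model$mean_shape,
    modes = apply(model$modes, 2L, identity, simplify = FALSE),
    eigenvalues = model$eigenvalues,
    n_modes_retained = model$n_modes_retained,
    clip_sd = model$clip_sd,
    n_points = model$n_points,
    n_training = model$n_training,
    vessel_label = model$vessel_label
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_shape_model
#' @export
read_shape_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$mean_shape)) stop("not a pcflow shape model file: ", path)
  n_points <- as.integer(obj$n_points)
  k <- as.integer(obj$n_modes_retained)
  modes <- if (k > 0L) {
    m <- obj$modes
    if (is.matrix(m)) t(m) else do.call(cbind, lapply(m, as.numeric))
  } else matrix(0, n_points, 0L)
  if (is.matrix(modes) && !is.null(dimnames(modes))) dimnames(modes) <- NULL
  structure(
    list(
      mean_shape = as.numeric(obj$mean_shape),
      modes = modes,
      eigenvalues = as.numeric(obj$eigenvalues),
      n_modes_retained = k,
      clip_sd = as.numeric(obj$clip_sd),
      n_points = n_points,
      n_training = as.integer(obj$n_training),
      vessel_label = obj$vessel_label
    ),
    class = "pc_shape_model"
  )
}
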