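#' Closed vessel contour
#'
#' A contour is an ordered, closed polygon in continuous image coordinates,
#' delineating the vessel lumen in one cardiac time phase. Coordinates are
#' 0-based with `x` along columns and `y` along rows; pixel centers sit at
#' integer coordinates. On construction the vertex order is normalized so the
#' shoelace signed area is positive.
#'
#' @param points numeric n x 2 matrix of (x, y) vertices, n >= 3. The polygon
#'   is implicitly closed (last vertex connects to the first).
#' @param phase_index 0-based cardiac phase the contour belongs to.
#' @param check if `TRUE`, verify the polygon is simple (non-self-intersecting).
#' @return An object of class `pc_contour`.
#' @seealso [contour_area()], [contour_mask()], [resample_contour()]
#' @export
pc_contour <- function(points, phase_index = 0L, check = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 3L) {
    stop("contour needs an n x 2 matrix with at least 3 points")
  }
  if (!all(is.finite(points))) stop("contour points must be finite")
  storage.mode(points) <- "double"
  dimnames(points) <- list(NULL, c("x", "y"))
  if (shoelace_area(points) < 0) points <- points[rev(seq_len(nrow(points))), , drop = FALSE]
  if (shoelace_area(points) <= 0) stop("contour has zero area")
  if (check && !polygon_is_simple(points)) stop("contour is self-intersecting")
  structure(
    list(points = points, phase_index = as.integer(phase_index), closed = TRUE),
    class = "pc_contour"
  )
}

#' @export
print.pc_contour <- function(x, ...) {
  cat(sprintf(
    "<pc_contour> %d vertices, phase %d, area %.2f px^2\n",
    nrow(x$points), x$phase_index, contour_area(x)
  ))
  invisible(x)
}

# signed shoelace area of an open-listed closed polygon
shoelace_area <- function(points) {
  x <- points[, 1L]; y <- points[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Polygon area by the shoelace formula
#'
#' @param c a [pc_contour()].
#' @return Area in square pixels (always positive).
#' @export
contour_area <- function(c) {
  stopifnot(inherits(c, "pc_contour"))
  abs(shoelace_area(c$points))
}

#' Area centroid of a contour
#'
#' @param c a [pc_contour()].
#' @return Length-2 numeric (x, y) of the polygon area centroid.
#' @export
contour_centroid <- function(c) {
  p <- c$points
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# O(n^2) pairwise proper-intersection test; n is small (tens of points)
polygon_is_simple <- function(points) {
  n <- nrow(points)
  seg <- cbind(points, points[c(2:n, 1L), , drop = FALSE])
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    # skip segments sharing an endpoint with i (adjacent in cyclic order)
    js <- js[js != i + 1L & !(i == 1L & js == n)]
    if (!length(js)) next
    a <- seg[i, 1:2]; b <- seg[i, 3:4]
    c1 <- seg[js, 1L]; c2 <- seg[js, 2L]; d1 <- seg[js, 3L]; d2 <- seg[js, 4L]
    o1 <- orient(a[1], a[2], b[1], b[2], c1, c2)
    o2 <- orient(a[1], a[2], b[1], b[2], d1, d2)
    o3 <- orient(c1, c2, d1, d2, a[1], a[2])
    o4 <- orient(c1, c2, d1, d2, b[1], b[2])
    if (any(o1 != o2 & o3 != o4 & o1 != 0 & o2 != 0 & o3 != 0 & o4 != 0)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Integer pixel centers inside a contour
#'
#' A pixel belongs to the interior when its center (integer coordinates) lies
#' inside the polygon under the even-odd rule. This single rule is shared by
#' flow sums, Dice overlap and median-velocity extraction.
#'
#' @param c a [pc_contour()].
#' @param dim optional image dim `c(H, W)` used to clip to valid pixels.
#' @return Integer m x 2 matrix of (x, y) pixel-center coordinates.
#' @export
interior_pixels <- function(c, dim = NULL) {
  p <- c$points
  xr <- range(p[, 1L]); yr <- range(p[, 2L])
  xs <- seq.int(ceiling(xr[1L]), floor(xr[2L]))
  ys <- seq.int(ceiling(yr[1L]), floor(yr[2L]))
  if (!is.null(dim)) {
    xs <- xs[xs >= 0L & xs <= dim[2L] - 1L]
    ys <- ys[ys >= 0L & ys <= dim[1L] - 1L]
  }
  if (!length(xs) || !length(ys)) {
    return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("x", "y"))))
  }
  grid <- cbind(x = rep(xs, times = length(ys)), y = rep(ys, each = length(xs)))
  inside <- mgcv::in.out(p, grid)
  out <- grid[inside, , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Rasterize a contour to a logical mask
#'
#' @param c a [pc_contour()].
#' @param grid image dim `c(H, W)`.
#' @return Logical H x W matrix; `mask[y + 1, x + 1]` is `TRUE` for interior
#'   pixel centers (x, y).
#' @export
contour_mask <- function(c, grid) {
  px <- interior_pixels(c, dim = grid)
  m <- matrix(FALSE, grid[1L], grid[2L])
  if (nrow(px)) m[cbind(px[, 2L] + 1L, px[, 1L] + 1L)] <- TRUE
  m
}

#' Resample a contour to uniform arc length
#'
#' Redistributes `n` vertices at equal arc-length spacing along the closed
#' polygon, starting from the first vertex. Used inside the active contour
#' iteration to keep vertices from bunching.
#'
#' @param c a [pc_contour()].
#' @param n number of output vertices.
#' @return A [pc_contour()] with `n` vertices.
#' @export
resample_contour <- function(c, n) {
  p <- resample_polygon(c$points, n)
  pc_contour(p, phase_index = c$phase_index, check = FALSE)
}

resample_polygon <- function(points, n) {
  pts <- rbind(points, points[1L, , drop = FALSE])
  d <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate contour: zero perimeter")
  target <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  x <- stats::approx(s, pts[, 1L], xout = target, ties = "ordered")$y
  y <- stats::approx(s, pts[, 2L], xout = target, ties = "ordered")$y
  cbind(x, y)
}

# bilinear interpolation of img (H x W, 0-based pixel centers) at continuous
# coordinates; coordinates are clamped to the image border
bilinear <- function(img, x, y) {
  H <- nrow(img); W <- ncol(img)
  x <- pmin(pmax(x, 0), W - 1L)
  y <- pmin(pmax(y, 0), H - 1L)
  x0 <- pmin(floor(x), W - 2L); y0 <- pmin(floor(y), H - 2L)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1L, x0 + 1L)
  v00 <- img[i00]
  v01 <- img[cbind(y0 + 1L, x0 + 2L)]
  v10 <- img[cbind(y0 + 2L, x0 + 1L)]
  v11 <- img[cbind(y0 + 2L, x0 + 2L)]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}
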