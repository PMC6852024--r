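ellipse_contour <- function(a, b, center = c(0, 0), n = 256L, phase = 0L,
                            rot = 0) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  x <- a * cos(th); y <- b * sin(th)
  pc_contour(cbind(center[1L] + x * cos(rot) - y * sin(rot),
                   center[2L] + x * sin(rot) + y * cos(rot)),
             phase_index = phase)
}

test_that("radial parameterization separates pose, scale and shape", {
  # circle: unit radii, scale = radius, center recovered, any n_points
  for (n in c(16L, 48L)) {
    sv <- parameterize_contour(circle_contour(10, c(33, 21), n = 256L), n)
    expect_equal(sv$radii, rep(1, n), tolerance = 5e-4)
    expect_equal(sv$scale, 10, tolerance = 5e-3)
    expect_equal(sv$centroid, c(33, 21), tolerance = 1e-6)
  }
  # axis-aligned ellipse a=12 b=8 sampled at 0/90/180/270 degrees
  sv <- parameterize_contour(ellipse_contour(12, 8), 4L)
  expect_equal(sv$radii * sv$scale, c(12, 8, 12, 8), tolerance = 1e-9)
  expect_equal(sv$scale, 10, tolerance = 1e-9)
})

test_that("parameterization inverts onto the original boundary", {
  c0 <- circle_contour(9, c(15, 15), n = 64L)
  back <- shape_to_contour(parameterize_contour(c0, 64L))
  r <- sqrt(rowSums(sweep(back$points, 2L, c(15, 15))^2))
  expect_true(all(abs(r - 9) < 0.1))
})

test_that("non-star-shaped contours are rejected with a named ray", {
  u <- pc_contour(cbind(c(0, 9, 9, 6, 6, 3, 3, 0),
                        c(0, 0, 9, 9, 3, 3, 9, 9)))
  expect_error(parameterize_contour(u, 32L), "ray at .*deg")
})

test_that("model fitting recovers the variation structure of the family", {
  expect_error(fit_shape_model(list(pc_segmentation(list(circle_contour(5)))),
                               n_points = 16L), "at least 2")
  # identical circles: zero eigenvalues, unit mean shape
  circles <- pc_segmentation(lapply(0:3, function(i)
    circle_contour(7, c(20, 20), phase = i)))
  m <- fit_shape_model(list(circles), n_points = 24L)
  expect_lt(max(m$eigenvalues), 1e-10)
  expect_equal(m$mean_shape, rep(1, 24L), tolerance = 1e-3)
  expect_identical(m$n_modes_retained, 0L)
  # circles of varying radius: scale normalization absorbs everything
  sizes <- pc_segmentation(lapply(0:4, function(i)
    circle_contour(5 + 2 * i, c(30, 30), phase = i)))
  m2 <- fit_shape_model(list(sizes), n_points = 24L)
  expect_lt(max(m2$eigenvalues), 1e-8)
  # aspect-ratio family: one dominant mode, matching an independent PCA
  ell <- pc_segmentation(lapply(0:9, function(i)
    ellipse_contour(10, 10 * (0.85 + 0.015 * i), phase = i)))
  m3 <- fit_shape_model(list(ell), n_points = 32L, variance_kept = 0.999)
  expect_gte(m3$eigenvalues[1L] / sum(m3$eigenvalues), 0.99)
  X <- t(vapply(ell$contours, function(c)
    parameterize_contour(c, 32L)$radii, numeric(32L)))
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  expect_equal(m3$eigenvalues[1:3], unname(pr$sdev[1:3]^2), tolerance = 1e-8)
  for (j in seq_len(min(2L, m3$n_modes_retained))) {
    agree <- abs(sum(m3$modes[, j] * pr$rotation[, j]))
    expect_equal(agree, 1, tolerance = 1e-6)
  }
})

test_that("modes are orthonormal and eigenvalues non-increasing", {
  m <- aorta_model()
  G <- crossprod(m$modes)
  expect_equal(G, diag(ncol(m$modes)), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  expect_lte(m$n_modes_retained, m$n_points)
})

test_that("reconstruction projects, clips, and preserves pose and scale", {
  m <- aorta_model()
  # the mean shape itself is a fixed point
  sv <- list(radii = m$mean_shape, scale = 11, centroid = c(40, 40),
             n_points = m$n_points, phase_index = 0L)
  class(sv) <- "pc_shapevec"
  mean_c <- shape_to_contour(sv)
  rec <- reconstruct_shape(mean_c, m)
  expect_equal(rec$points, mean_c$points, tolerance = 1e-6)
  # in-subspace shape within the clip bounds is unchanged
  b <- c(1.5 * sqrt(m$eigenvalues[1L]), -0.8 * sqrt(m$eigenvalues[2L]))
  sv$radii <- m$mean_shape + drop(m$modes[, 1:2] %*% b)
  in_sub <- shape_to_contour(sv)
  rec2 <- reconstruct_shape(in_sub, m)
  expect_equal(rec2$points, in_sub$points, tolerance = 1e-6)
  # a far excursion along mode 1 is clipped to exactly clip_sd SD
  sv$radii <- m$mean_shape + 6 * sqrt(m$eigenvalues[1L]) * m$modes[, 1L]
  far <- shape_to_contour(sv)
  rec3 <- reconstruct_shape(far, m)
  coef <- crossprod(m$modes, parameterize_contour(rec3, m$n_points)$radii -
                      m$mean_shape)
  expect_equal(coef[1L] / sqrt(m$eigenvalues[1L]), m$clip_sd,
               tolerance = 1e-6)
})

test_that("reconstruction is idempotent and error shrinks with more modes", {
  m <- aorta_model()
  target <- ellipse_contour(12, 9.5, c(48, 48), rot = 0.1)
  once <- reconstruct_shape(target, m)
  twice <- reconstruct_shape(once, m)
  expect_equal(twice$points, once$points, tolerance = 1e-9)
  # centroid and mean radius preserved
  sv_in <- parameterize_contour(target, m$n_points)
  sv_out <- parameterize_contour(once, m$n_points)
  expect_equal(sv_out$centroid, sv_in$centroid, tolerance = 1e-8)
  expect_equal(sv_out$scale, sv_in$scale, tolerance = 1e-8)
  # reconstruction error is non-increasing in the number of retained modes
  mfull <- fit_shape_model(generate_training_set(12L, "aorta", seed = 7L),
                           variance_kept = 0.9999, vessel_label = "aorta")
  errs <- vapply(seq_len(min(8L, mfull$n_modes_retained)), function(k) {
    mk <- mfull
    mk$n_modes_retained <- k
    mk$modes <- mfull$modes[, seq_len(k), drop = FALSE]
    rk <- reconstruct_shape(target, mk)
    sqrt(mean((parameterize_contour(rk, mfull$n_points)$radii -
                 sv_in$radii)^2))
  }, numeric(1L))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("shape models serialize to JSON and back", {
  m <- aorta_model()
  f <- tempfile(fileext = ".json")
  write_shape_model(m, f)
  r <- read_shape_model(f)
  expect_equal(r$mean_shape, m$mean_shape)
  expect_equal(r$modes, m$modes, ignore_attr = TRUE)
  expect_equal(r$eigenvalues, m$eigenvalues)
  expect_identical(r$n_modes_retained, m$n_modes_retained)
  expect_identical(r$vessel_label, m$vessel_label)
})
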