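test_that("motion tracker recovers known integer shifts exactly", {
  set.seed(5)
  a <- matrix(stats::rnorm(80 * 80), 80, 80)
  roi <- circle_contour(9, c(40, 40), n = 32L)
  expect_equal(track_rigid_motion(a, a, roi, 10L), c(dx = 0, dy = 0))
  # translate content by (dx, dy) = (3, -2)
  shift_img <- function(img, dx, dy) {
    H <- nrow(img); W <- ncol(img)
    out <- matrix(0, H, W)
    ys <- 1:H; xs <- 1:W
    out[pmin(pmax(ys - dy, 1L), H), pmin(pmax(xs - dx, 1L), W)] <- 0  # init
    for (y in ys) for (x in xs) {
      yy <- y + dy; xx <- x + dx
      if (yy >= 1 && yy <= H && xx >= 1 && xx <= W) out[yy, xx] <- img[y, x]
    }
    out
  }
  for (s in list(c(3, -2), c(-5, 4), c(0, 7))) {
    b <- shift_img(a, s[1L], s[2L])
    expect_equal(track_rigid_motion(a, b, roi, 10L),
                 c(dx = s[1L], dy = s[2L]))
    # exhaustive-shift oracle without pre-smoothing agrees
    expect_equal(track_rigid_motion(a, b, roi, 10L, smooth_sigma = 0),
                 c(dx = s[1L], dy = s[2L]))
  }
  # featureless images: all correlations tie, broken toward zero shift
  flat <- matrix(2, 80, 80)
  expect_equal(track_rigid_motion(flat, flat, roi, 6L), c(dx = 0, dy = 0))
  # patch + maximal shift must stay inside the image
  edge_roi <- circle_contour(9, c(12, 40), n = 32L)
  expect_error(track_rigid_motion(a, a, edge_roi, 10L), "leaves the image")
})

test_that("median velocity inside a contour is the spatial median", {
  mkvel <- function(vals) {
    v <- array(0, c(2, 6, 6))
    v[1, 1, seq_along(vals)] <- vals  # pixels (x = 0.., y = 0)
    structure(list(velocity = v, corrected = FALSE), class = "pc_velocity")
  }
  row3 <- rect_contour(0, 2, 0, 0)      # pixel centers (0,0),(1,0),(2,0)
  expect_equal(median_velocity_inside(mkvel(c(1, 2, 100)), 0L, row3), 2)
  expect_equal(median_velocity_inside(mkvel(c(5, 5, 5)), 0L, row3), 5)
  one <- rect_contour(1, 1, 0, 0)
  expect_equal(median_velocity_inside(mkvel(c(0, -7)), 0L, one), -7)
  tiny <- pc_contour(cbind(c(4.6, 4.9, 4.75), c(4.6, 4.6, 4.9)))
  expect_error(median_velocity_inside(mkvel(1), 0L, tiny), "no pixel centers")
})

test_that("velocity clustering matches exhaustive within-class-variance search", {
  expect_equal(cluster_time_phases(c(10, 10, 100, 100))$high, c(2L, 3L))
  expect_equal(cluster_time_phases(c(5, 50, 55, 6, 4))$high, c(1L, 2L))
  expect_warning(out <- cluster_time_phases(c(0, 0, 0, 0)), "degenerate")
  expect_equal(out$high, 0:3)
  set.seed(9)
  for (i in 1:20) {
    T_ <- sample(3:12, 1L)
    x <- round(stats::runif(T_, 0, 100), 2)
    got <- cluster_time_phases(x)
    expect_equal(got$high, exhaustive_two_partition(abs(x)),
                 info = paste("case", i))
    expect_equal(sort(c(got$high, got$low)), 0:(T_ - 1L))
  }
})

test_that("processing order walks the high-velocity interval then outward", {
  expect_equal(processing_order(c(3, 4, 5), 4L, 10L),
               c(4L, 5L, 3L, 6L, 7L, 8L, 9L, 2L, 1L, 0L))
  expect_equal(processing_order(0:2, 0L, 3L), c(0L, 1L, 2L))
  expect_equal(processing_order(4L, 4L, 5L), c(4L, 3L, 2L, 1L, 0L))
  # seed outside the high class: start at the absolute-median maximum
  med <- c(1, 2, 50, 60, 55, 3, 2, 1)
  cls <- cluster_time_phases(med)
  ord <- processing_order(cls$high, 7L, 8L, med)
  expect_equal(ord[1L], 3L)
  # adjacency invariant on random high sets
  set.seed(4)
  for (i in 1:25) {
    T_ <- sample(4:14, 1L)
    med <- stats::runif(T_, 0, 100)
    cls <- cluster_time_phases(med)
    ord <- processing_order(cls$high, sample(0:(T_ - 1L), 1L), T_, med)
    expect_equal(sort(ord), 0:(T_ - 1L))
    seen <- ord[1L]
    for (p in ord[-1L]) {
      expect_true((p - 1L) %in% seen || (p + 1L) %in% seen)
      seen <- c(seen, p)
    }
  }
})

test_that("active contour obeys force limits and converges onto edges", {
  # zero forces leave a uniformly-sampled contour unchanged
  circ <- circle_contour(10, c(40, 40), n = 48L)
  img <- matrix(1, 96, 96)
  p0 <- algorithm_params(edge_weight = 0, tension_weight = 0,
                         rigidity_weight = 0)
  expect_equal(deform_active_contour(circ, img, p0)$points, circ$points,
               tolerance = 1e-9)
  # pure tension is a curve-shortening flow: area decreases monotonically
  pt <- algorithm_params(edge_weight = 0, tension_weight = 0.2,
                         rigidity_weight = 0, snake_iterations = 20L)
  areas <- numeric(5L)
  cur <- circ
  for (i in 1:5) {
    cur <- deform_active_contour(cur, img, pt)
    areas[i] <- contour_area(cur)
  }
  expect_true(all(diff(c(contour_area(circ), areas)) < 0))
  # a circle seeded 2 px inside a high-contrast disk finds the boundary
  xs <- matrix(rep(0:95, each = 96), 96, 96)
  ys <- matrix(rep(0:95, times = 96), 96, 96)
  disk <- EBImage::gblur(
    ifelse((xs - 47.5)^2 + (ys - 47.5)^2 <= 13^2, 3, 1), 1)
  seed <- circle_contour(11, c(47.5, 47.5), n = 48L)
  out <- deform_active_contour(seed, disk, algorithm_params())
  r <- sqrt(rowSums(sweep(out$points, 2L, c(47.5, 47.5))^2))
  expect_lt(mean(abs(r - 13)), 0.5)
})

test_that("contour rescaling is a similarity transform about the centroid", {
  circ <- circle_contour(10, c(30, 28), n = 40L)
  expect_equal(rescale_contour(circ, 1)$points, circ$points)
  up <- rescale_contour(circ, 1.05)
  r <- sqrt(rowSums(sweep(up$points, 2L, c(30, 28))^2))
  expect_equal(r, rep(10.5, 40L), tolerance = 1e-9)
  expect_equal(contour_centroid(up), contour_centroid(circ), tolerance = 1e-9)
  # area scales with the square of the factor for any polygon
  blob <- pc_contour(cbind(c(0, 8, 9, 4, -1), c(0, -1, 6, 9, 5)))
  expect_equal(contour_area(rescale_contour(blob, 1.3)),
               1.3^2 * contour_area(blob), tolerance = 1e-9)
})

test_that("segmentation tracks a static high-contrast vessel precisely", {
  gen <- generate_phantom_series(tiny_spec(contrast_range = c(3, 3)))
  seg <- segment_series(gen$series, gen$truth$contours[[2L]],
                        near_circle_model(), algorithm_params())
  dv <- dice_vec(seg, gen$truth, dim(gen$series$magnitude)[2:3])
  expect_true(all(dv > 0.97))
  expect_equal(seg$shifts, matrix(0, 8L, 2L))
})

test_that("known integer motion is recovered and segmentation follows it", {
  path <- cbind(c(0, 1, 3, 4, 4, 3, 1, 0), c(0, -1, -2, -2, -1, 0, 1, 1))
  gen <- generate_phantom_series(
    tiny_spec(center_path = path, contrast_range = c(3, 3)))
  seg <- segment_series(gen$series, gen$truth$contours[[2L]],
                        near_circle_model(), algorithm_params())
  dv <- dice_vec(seg, gen$truth, dim(gen$series$magnitude)[2:3])
  expect_true(all(dv > 0.95))
  # applied initialization shifts equal the ground-truth per-step motion
  true_steps <- diff(path)
  for (t in 2:8) {
    ord_t <- which(seg$processing_order == t - 1L)
    ord_prev <- which(seg$processing_order == t - 2L)
    if (ord_prev < ord_t) {
      expect_equal(unname(seg$shifts[t, ]), unname(true_steps[t - 1L, ]))
    }
  }
})

test_that("segmentation is deterministic and annotates failures with phase", {
  gen <- generate_phantom_series(tiny_spec())
  s1 <- segment_series(gen$series, gen$truth$contours[[2L]],
                       near_circle_model(), algorithm_params())
  s2 <- segment_series(gen$series, gen$truth$contours[[2L]],
                       near_circle_model(), algorithm_params())
  expect_identical(s1, s2)
  expect_error(segment_series(gen$series, gen$truth$contours[[2L]],
                              aorta_model(),
                              algorithm_params(search_radius = 40L)),
               "motion tracking failed")
})

test_that("a circle-trained model keeps outputs near-circular under noise", {
  model <- fit_shape_model(
    generate_training_set(6L, "aorta", seed = 3L, aspect_range = c(1, 1),
                          harmonic_amp = 0),
    vessel_label = "aorta"
  )
  gen <- generate_phantom_series(tiny_spec(noise_sigma_magnitude = 0.2))
  seg <- segment_series(gen$series, gen$truth$contours[[2L]], model,
                        algorithm_params())
  for (ct in seg$contours) {
    ctr <- contour_centroid(ct)
    r <- sqrt(rowSums(sweep(ct$points, 2L, ctr)^2))
    expect_lt(max(r) / min(r), 1.05)
  }
})
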