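plane_velocity <- function(a, b, c, T_ = 3L, H = 20L, W = 20L, extra = 0) {
  xs <- matrix(rep(0:(W - 1L), each = H), H, W)
  ys <- matrix(rep(0:(H - 1L), times = W), H, W)
  plane <- a + b * xs + c * ys
  v <- array(rep(plane, each = T_), c(T_, H, W)) + extra
  structure(list(velocity = v, corrected = FALSE), class = "pc_velocity")
}

test_that("background plane is recovered exactly from noiseless static tissue", {
  vel <- plane_velocity(0.5, 0.01, -0.02)
  mask <- matrix(TRUE, 20, 20)
  out <- linear_background_correction(vel, mask)
  expect_true(out$corrected)
  expect_equal(attr(out, "plane"), c(0.5, 0.01, -0.02), tolerance = 1e-10)
  expect_lt(max(abs(out$velocity)), 1e-10)
  # zero background: output equals input
  vel0 <- plane_velocity(0, 0, 0)
  out0 <- linear_background_correction(vel0, mask)
  expect_equal(out0$velocity, vel0$velocity, tolerance = 1e-12)
  # idempotence: refitting corrected data finds a null plane
  again <- linear_background_correction(out, mask)
  expect_lt(max(abs(attr(again, "plane"))), 1e-10)
})

test_that("plane recovery tolerates noise at the least-squares rate", {
  set.seed(21)
  H <- 40L; W <- 25L  # 1000 static pixels
  vel <- plane_velocity(0.5, 0.01, -0.02, T_ = 1L, H = H, W = W,
                        extra = array(stats::rnorm(H * W, 0, 0.1), c(1, H, W)))
  out <- linear_background_correction(vel, matrix(TRUE, H, W))
  expect_lt(abs(attr(out, "plane")[1L] - 0.5), 0.02)
})

test_that("degenerate static masks are rejected", {
  vel <- plane_velocity(1, 0, 0)
  small <- matrix(FALSE, 20, 20); small[1, 1:5] <- TRUE
  expect_error(linear_background_correction(vel, small), "at least 10")
  line <- matrix(FALSE, 20, 20); line[3, ] <- TRUE
  expect_error(linear_background_correction(vel, line), "collinear")
})

test_that("flow is the velocity sum times pixel area, in ml/s", {
  v <- array(0, c(2, 20, 20))
  v[1, 1:10, 1:10] <- 50
  vel <- structure(list(velocity = v, corrected = TRUE),
                   class = "pc_velocity")
  roi <- rect_contour(0, 9, 0, 9)   # exactly the 100 pixels at 50 cm/s
  expect_equal(flow_per_phase(vel, roi, c(1, 1)), 50)        # ml/s
  roi2 <- roi; roi2$phase_index <- 1L
  expect_equal(flow_per_phase(vel, roi2, c(1, 1)), 0)
  # antisymmetric velocity integrates to zero
  v2 <- array(0, c(1, 20, 20)); v2[1, 1:5, 1:10] <- 30; v2[1, 6:10, 1:10] <- -30
  vel2 <- structure(list(velocity = v2, corrected = TRUE),
                    class = "pc_velocity")
  expect_equal(flow_per_phase(vel2, roi, c(1, 1)), 0)
  # linear in velocity, additive over disjoint contours
  top <- rect_contour(0, 9, 0, 4); bottom <- rect_contour(0, 9, 5, 9)
  expect_equal(flow_per_phase(vel, top, c(1, 1)) +
                 flow_per_phase(vel, bottom, c(1, 1)),
               flow_per_phase(vel, roi, c(1, 1)))
  # pixel area enters quadratically via spacing
  expect_equal(flow_per_phase(vel, roi, c(2, 2)),
               4 * flow_per_phase(vel, roi, c(1, 1)))
})

test_that("net volume is the time-sum of flow", {
  expect_equal(net_flow_volume(rep(100, 30L), 20), 60)
  expect_equal(net_flow_volume(numeric(30L), 25), 0)
  # Riemann refinement: halving dt with interpolated flows preserves volume
  f <- function(t) 100 * sin(pi * t)^2
  coarse <- net_flow_volume(f((0:29) / 30), 30)
  fine <- net_flow_volume(f((0:59) / 60), 15)
  expect_lt(abs(coarse - fine) / fine, 0.01)
})

test_that("cardiac index and Qp/Qs follow their defining formulas", {
  expect_equal(cardiac_index(70, 857, 1.9), 70 * (60000 / 857) / 1.9 / 1000)
  expect_equal(round(cardiac_index(70, 857, 1.9), 2), 2.58)
  expect_equal(cardiac_index(0, 857, 1.9), 0)
  expect_equal(cardiac_index(70, 857, 3.8), cardiac_index(70, 857, 1.9) / 2)
  expect_error(cardiac_index(70, 857, 0), "bsa")
  expect_equal(qp_qs(40, 40), 1)
  expect_equal(qp_qs(80, 40), 2)
  expect_error(qp_qs(40, 0), "positive")
})

test_that("the default static mask excludes the moving lumen", {
  gen <- generate_phantom_series(tiny_spec())
  mask <- static_tissue_mask(gen$series)
  expect_gte(sum(mask), 10L)
  lumen <- contour_mask(gen$truth$contours[[1L]],
                        dim(gen$series$magnitude)[2:3])
  expect_lt(sum(mask & lumen) / sum(lumen), 0.05)
})

test_that("quantify_flow corrects the background and integrates the cycle", {
  spec <- tiny_spec(background_plane = c(0.8, 0.01, -0.02))
  gen <- generate_phantom_series(spec)
  fl <- quantify_flow(gen$series, gen$truth, bsa = 1.9)
  expect_true(fl$corrected)
  expect_equal(fl$net_volume, gen$true_net_volume, tolerance = 0.02)
  expect_equal(fl$heart_rate, 60000 / 900)
  expect_equal(fl$cardiac_index,
               cardiac_index(fl$net_volume, 900, 1.9))
  # without correction the plane offset inflates the volume
  fl_raw <- quantify_flow(gen$series, gen$truth, correct_background = FALSE)
  expect_gt(abs(fl_raw$net_volume - gen$true_net_volume),
            abs(fl$net_volume - gen$true_net_volume))
})
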