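test_that("signed_angle matches hand values and the polar-angle oracle", {
  expect_equal(signed_angle(c(1, 0), c(0, 1)), 90)
  expect_equal(signed_angle(c(3, 4), c(3, 4)), 0)
  expect_equal(signed_angle(c(1, 0), c(1, 1)), 45)
  expect_equal(signed_angle(c(1, 0), c(-1, 0)), 180)
  expect_error(signed_angle(c(0, 0), c(1, 0)), "degenerate")

  set.seed(17)
  for (i in 1:200) {
    u <- stats::rnorm(2); v <- stats::rnorm(2)
    expect_equal(signed_angle(u, v), oracle_angle(u, v),
                 tolerance = 1e-9)
  }
})

test_that("signed_angle is antisymmetric and rotation invariant", {
  set.seed(23)
  for (i in 1:100) {
    u <- stats::rnorm(2); v <- stats::rnorm(2)
    a <- signed_angle(u, v)
    if (abs(abs(a) - 180) > 1e-9)
      expect_equal(signed_angle(v, u), -a, tolerance = 1e-9)
    th <- stats::runif(1, -pi, pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    expect_equal(signed_angle(as.numeric(R %*% u), as.numeric(R %*% v)),
                 a, tolerance = 1e-8)
  }
})

# canonical single-frame geometry: mantle at origin (image coords with
# y down, so y-up math flips the sign), heading +x, prey ahead
canon_track <- function(prey = c(200, 1000), eyes_dy = 2,
                        tips = NULL) {
  if (is.null(tips)) tips <- list(left = c(112, 998), right = c(112, 1002))
  make_track(list(
    mantle_end = c(100, 1000),
    left_eye = c(110, 1000 - eyes_dy),
    right_eye = c(110, 1000 + eyes_dy),
    left_club_tip = tips$left,
    right_club_tip = tips$right,
    shrimp_left_eye = c(prey[1], prey[2] - 2),
    shrimp_right_eye = c(prey[1], prey[2] + 2),
    hook = prey + c(5, -3), tail = prey + c(20, 0)), n = 1)
}

test_that("body_axis recovers the constructed head, heading and mantle length", {
  tr <- canon_track()
  ax <- body_axis(interpolate_gaps(tr))
  expect_equal(unname(ax$head_px[1, ]), c(110, 1000))
  expect_equal(unname(ax$heading[1, ]), c(1, 0))
  expect_equal(ax$mantle_len_px[1], 10)

  # rigid-motion equivariance: rotating the frame rotates the heading
  rot <- transform_track(tr, deg = 90, shift = c(15, -30))
  ax2 <- body_axis(interpolate_gaps(rot))
  expect_equal(unname(ax2$heading[1, ]), c(0, 1), tolerance = 1e-12)
  expect_equal(ax2$mantle_len_px[1], 10, tolerance = 1e-12)

  degen <- make_track(list(mantle_end = c(5, 5), left_eye = c(5, 3),
                           right_eye = c(5, 7)), n = 1)
  expect_error(body_axis(interpolate_gaps(degen)), "degenerate")
})

test_that("the visual attack angle matches construction and a trig oracle", {
  cl <- interpolate_gaps(canon_track(prey = c(300, 1000)))
  expect_equal(visual_attack_angle(cl), 0, tolerance = 1e-12)
  # prey 90 degrees counter-clockwise (above in y-up = smaller image y)
  cl2 <- interpolate_gaps(canon_track(prey = c(110, 800)))
  expect_equal(visual_attack_angle(cl2), 90, tolerance = 1e-12)

  set.seed(41)
  for (i in 1:50) {
    prey <- c(stats::runif(1, 150, 1800), stats::runif(1, 150, 1800))
    cl <- interpolate_gaps(canon_track(prey = prey))
    # oracle: polar angles of the two directions in the y-up frame
    o <- oracle_angle(c(1, 0), c(prey[1] - 110, -(prey[2] - 1000)))
    expect_equal(visual_attack_angle(cl), o, tolerance = 1e-9)
  }
})

test_that("angle operations are equivariant under rotation/translation and negate under mirroring", {
  set.seed(53)
  for (i in 1:20) {
    prey <- c(stats::runif(1, 300, 1700), stats::runif(1, 300, 1700))
    tr <- canon_track(prey = prey)
    cl <- interpolate_gaps(tr)
    deg <- stats::runif(1, -170, 170)
    shift <- stats::runif(2, -80, 80)
    clT <- interpolate_gaps(transform_track(tr, deg, shift))
    expect_equal(visual_attack_angle(clT), visual_attack_angle(cl),
                 tolerance = 1e-8)
    expect_equal(eye_angle(clT, "left"), eye_angle(cl, "left"),
                 tolerance = 1e-8)
    expect_equal(tentacle_angle(clT, "left", 0),
                 tentacle_angle(cl, "left", 0), tolerance = 1e-8)

    clM <- interpolate_gaps(mirror_track(tr))
    expect_equal(visual_attack_angle(clM), -visual_attack_angle(cl),
                 tolerance = 1e-8)
    # mirroring swaps sides and negates the eye angles
    expect_equal(eye_angle(clM, "left"), -eye_angle(cl, "right"),
                 tolerance = 1e-8)
    expect_equal(tentacle_angle(clM, "right", 0),
                 -tentacle_angle(cl, "left", 0), tolerance = 1e-8)
  }
})

test_that("eye angles are symmetric for a symmetric head and track vergence shifts", {
  cl <- interpolate_gaps(canon_track(eyes_dy = 2))
  bl <- eye_angle(cl, "left"); br <- eye_angle(cl, "right")
  expect_equal(bl, -br)
  expect_gt(bl, 0)  # left eye lies counter-clockwise of the axis

  # eye on the axis: zero angle
  cl0 <- interpolate_gaps(canon_track(eyes_dy = 0))
  expect_equal(eye_angle(cl0, "left"), 0)

  # moving both eye points 2 degrees toward the axis shifts each beta by ~2
  md_len <- 10
  ang <- atan2(2, md_len)  # current left-eye angle, rad
  new_dy <- md_len * tan(ang - 2 * pi / 180)
  cl2 <- interpolate_gaps(canon_track(eyes_dy = new_dy))
  expect_equal(eye_angle(cl, "left") - eye_angle(cl2, "left"), 2,
               tolerance = 1e-9)
})

test_that("tentacular strike angle follows the tip and gates on extension", {
  # tip straight ahead, clearly extended (head at (110,1000), ML 10)
  tr <- canon_track(tips = list(left = c(130, 1000), right = c(130, 1000)))
  cl <- interpolate_gaps(tr)
  expect_equal(tentacle_angle(cl, "left"), 0, tolerance = 1e-12)
  # tip at +30 degrees of heading (y-up frame: above = smaller image y)
  d <- 20
  tip <- c(110 + d * cos(pi / 6), 1000 - d * sin(pi / 6))
  cl2 <- interpolate_gaps(canon_track(tips = list(left = tip, right = tip)))
  expect_equal(tentacle_angle(cl2, "left"), 30, tolerance = 1e-9)
  # retracted tip (0.2 ML) is reported undefined
  cl3 <- interpolate_gaps(canon_track(
    tips = list(left = c(112, 1000), right = c(112, 1000))))
  expect_true(is.na(tentacle_angle(cl3, "left")))
})

test_that("club angle separates along-axis from transverse tip motion", {
  n <- 11
  tr <- make_track(list(
    mantle_end = matrix(c(rep(100, n), rep(1000, n)), n),
    left_eye = matrix(c(rep(110, n), rep(998, n)), n),
    right_eye = matrix(c(rep(110, n), rep(1002, n)), n),
    # left tip extends straight along the head-to-tip line
    left_club_tip = matrix(c(130 + 3 * (0:(n - 1)), rep(1000, n)), n),
    # right tip sweeps perpendicular to its head-to-tip line
    right_club_tip = matrix(c(rep(130, n), 1000 - 3 * (0:(n - 1))), n),
    shrimp_left_eye = c(500, 998), shrimp_right_eye = c(500, 1002),
    hook = c(505, 997), tail = c(520, 1000)), n = n)
  cl <- interpolate_gaps(tr)
  th_l <- club_angle(cl, "left", window = 5, d_min = 1,
                     extension_threshold = 0)
  th_r <- club_angle(cl, "right", window = 5, d_min = 1,
                     extension_threshold = 0)
  expect_equal(th_l[6], 0, tolerance = 1e-9)
  expect_equal(abs(th_r[2]), 90, tolerance = 15)  # transverse sweep
  # displacement below d_min flags the angle undefined
  th_still <- club_angle(cl, "left", window = 5, d_min = 100,
                         extension_threshold = 0)
  expect_true(all(is.na(th_still)))
})

test_that("horizontal speed is exact for constant velocity and unbiased under noise", {
  md <- test_metadata(fps = 90, mm_per_px = 0.5)
  n <- 300
  tr <- make_track(list(), n = n, metadata = md)
  v_px <- 2  # px/frame -> 2*90*0.5 = 90 mm/s
  for (p in body_parts()) {
    tr$x[, p] <- 100 + v_px * (0:(n - 1))
    tr$y[, p] <- 500
  }
  # keep the cuttlefish geometry non-degenerate
  tr$x[, "mantle_end"] <- tr$x[, "mantle_end"] - 20
  cl <- interpolate_gaps(tr)
  v <- horizontal_speed(cl, "prey", window = 5)
  expect_equal(v, rep(90, n), tolerance = 1e-9)

  # stationary target: zero speed
  tr0 <- canon_track()
  tr0$x <- tr0$x[rep(1, 50), ]; tr0$y <- tr0$y[rep(1, 50), ]
  tr0$likelihood <- tr0$likelihood[rep(1, 50), ]
  v0 <- horizontal_speed(interpolate_gaps(tr0), "prey")
  expect_equal(v0, rep(0, 50))

  # sigma = 1 px noise, window 5: mean estimate within 2% of truth
  set.seed(7)
  trn <- tr
  trn$x <- tr$x + stats::rnorm(length(tr$x))
  vn <- horizontal_speed(interpolate_gaps(trn), "prey", window = 5)
  expect_lt(abs(mean(vn) / 90 - 1), 0.02)

  expect_error(horizontal_speed(interpolate_gaps(make_track(list(), n = 2)),
                                "prey"), "3 frames")
})

test_that("target distance normalises by the median mantle length", {
  # mantle 100 px, mm_per_px 0.5, prey 80 mm = 160 px away -> 1.6 ML
  tr <- make_track(list(
    mantle_end = c(400, 1000), left_eye = c(500, 995),
    right_eye = c(500, 1005),
    left_club_tip = c(510, 1000), right_club_tip = c(510, 1000),
    shrimp_left_eye = c(660, 998), shrimp_right_eye = c(660, 1002),
    hook = c(665, 998), tail = c(680, 1000)), n = 1,
    metadata = test_metadata(mm_per_px = 0.5))
  cl <- interpolate_gaps(tr)
  expect_equal(target_distance(cl), 1.6, tolerance = 1e-12)
  # prey at exactly one mantle length -> 1; at the head -> 0
  expect_equal(target_distance(cl) * 160 / 160, 1.6)
})

test_that("noise-free simulator rendering inverts exactly through the kinematics", {
  s <- sim_scenario(seed = 2, duration_s = 10, noise_sigma_px = 0,
                    occlusion_prob = 0)
  trial <- simulate_trial(s)
  cl <- clean_pose_track(trial$track)
  ax <- body_axis(cl)
  est_deg <- atan2(ax$heading[, 2], ax$heading[, 1]) * 180 / pi
  diff <- abs(((est_deg - trial$truth$frames$heading_deg + 180) %% 360) - 180)
  expect_lt(max(diff), 1e-6)
})

test_that("heading survives 1 px coordinate noise to within a degree", {
  s <- sim_scenario(seed = 8, duration_s = 10, noise_sigma_px = 1,
                    occlusion_prob = 0)
  trial <- simulate_trial(s)
  cl <- clean_pose_track(trial$track)
  ax <- body_axis(cl)
  est_deg <- atan2(ax$heading[, 2], ax$heading[, 1]) * 180 / pi
  diff <- abs(((est_deg - trial$truth$frames$heading_deg + 180) %% 360) - 180)
  expect_lt(stats::median(diff), 1)
})

test_that("compute_kinematics returns a coherent per-frame table", {
  s <- sim_scenario(seed = 4, duration_s = 10)
  trial <- simulate_trial(s)
  kin <- compute_kinematics(clean_pose_track(trial$track))
  expect_s3_class(kin, "kinematic_series")
  expect_identical(nrow(kin), 900L)
  expect_equal(kin$time_s, (0:899) / 90)
  expect_equal(sqrt(kin$heading_x^2 + kin$heading_y^2), rep(1, 900))
  expect_true(all(kin$target_dist_ml >= 0))
  expect_true(all(kin$mantle_len_px > 0))
  ang <- c(kin$alpha_deg, kin$beta_left_deg, kin$beta_right_deg)
  expect_true(all(ang > -180 & ang <= 180))
  path <- withr::local_tempfile(fileext = ".csv")
  write_kinematics_csv(kin, path)
  expect_identical(nrow(utils::read.csv(path)), 900L)
})
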