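test_that("rigid alignment recovers exact transforms and matches a brute-force fit", {
  mesh <- toy_mesh(40)
  ref <- mesh$coords
  # identity
  fit0 <- rigid_align(ref, ref)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit0$translation, c(0, 0, 0) , tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(fit0$residual, 0, tolerance = 1e-12)
  # known rotation + translation, recovered to 1e-8
  R0 <- rot_axis(c(1, 2, -1), 0.7)
  tr0 <- c(0.3, -0.2, 0.5)
  frame <- ref %*% t(R0) + matrix(tr0, nrow(ref), 3, byrow = TRUE)
  fit <- rigid_align(frame, ref)
  expect_lt(max(abs(fit$rotation - R0)), 1e-8)
  expect_lt(max(abs(fit$translation - tr0)), 1e-8)
  expect_lt(fit$residual, 1e-8)
  # noisy frame: SVD solution matches a direct Euler-angle minimization
  set.seed(31)
  noisy <- frame + matrix(rnorm(length(frame), sd = 0.01), nrow(frame))
  fit_n <- rigid_align(noisy, ref)
  brute <- brute_rigid_align(noisy, ref)
  expect_equal(fit_n$residual, brute$residual, tolerance = 1e-4)
  expect_lt(max(abs(fit_n$rotation - brute$rotation)), 1e-3)
  expect_equal(fit_n$residual, 0.01 * sqrt(3), tolerance = 0.15)
})

test_that("rigid alignment rejects degenerate point sets", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(rigid_align(line, line), "collinear")
  expect_error(rigid_align(diag(3), diag(3), index_set = 1:2), "at least 3")
})

test_that("compiled rigid pose series matches the exported single-frame solver", {
  mesh <- toy_mesh(32)
  traj <- generate_actor_motion(mesh, actor_motion_params(), 2, 30, seed = 8)
  pose <- rigid_pose_series(traj)
  idx <- mesh$region_map$head_rigid
  for (t in c(1, 17, 60)) {
    single <- rigid_align(traj$coords[t, , ], mesh$coords, index_set = idx)
    expect_equal(pose$rotation[, , t], single$rotation, tolerance = 1e-10)
    expect_equal(pose$translation[t, ], single$translation, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(pose$residual[t], single$residual, tolerance = 1e-10)
  }
})

test_that("head motion magnitude has the closed forms for pure translation and rotation", {
  mesh <- toy_mesh(36)
  traj <- static_trajectory(mesh, T = 20)
  expect_equal(head_motion_series(traj), rep(0, 20), tolerance = 1e-12)
  # pure per-frame translation by v: magnitude = ||v|| each frame
  v <- c(0.01, -0.02, 0.005)
  moved <- traj
  for (t in 1:20) moved$coords[t, , ] <- sweep(mesh$coords, 2, (t - 1) * v, `+`)
  hs <- head_motion_series(moved)
  expect_equal(hs[-1], rep(sqrt(sum(v^2)), 19), tolerance = 1e-6)
  # pure rotation at constant angular step about the head-region centroid:
  # reported magnitude (arc) matches the mean per-point chord displacement
  idx <- mesh$region_map$head_rigid
  cen <- colMeans(mesh$coords[idx, ])
  theta <- 0.001
  rot <- traj
  for (t in 1:20) {
    R <- rot_z((t - 1) * theta)
    rot$coords[t, , ] <- sweep(sweep(mesh$coords, 2, cen) %*% t(R), 2, cen, `+`)
  }
  hs_rot <- head_motion_series(rot)
  chord12 <- mean(sqrt(rowSums((rot$coords[2, idx, ] - rot$coords[1, idx, ])^2)))
  chord45 <- mean(sqrt(rowSums((rot$coords[5, idx, ] - rot$coords[4, idx, ])^2)))
  expect_equal(hs_rot[2], chord12, tolerance = 1e-6)
  expect_equal(hs_rot[5], chord45, tolerance = 1e-6)
})

test_that("rigid-removed region series vanish under purely rigid motion", {
  mesh <- toy_mesh(48)
  traj <- generate_actor_motion(
    mesh, actor_motion_params(blink_amp = 0, mouth_amp = 0, noise_sd = 0),
    4, 30, seed = 5
  )
  for (region in c("left_periocular", "right_periocular", "perioral")) {
    expect_lt(max(region_motion_series(traj, region, remove_rigid = TRUE)), 1e-6)
  }
  expect_gt(max(region_motion_series(traj, "perioral", remove_rigid = FALSE)), 1e-4)
  expect_error(region_motion_series(traj, "nose"), "unknown region")
})

test_that("moving distance has its closed forms", {
  expect_equal(moving_distance(rep(0, 100)), 0)
  # one landmark stepping (0,0,0) -> (3,4,0): 3-4-5 case through the
  # region-series route on a 1-landmark region
  series <- c(0, 5)
  expect_equal(moving_distance(series), 5)
  # sampled sinusoid: total variation 4 A f T within 2%
  A <- 0.5; f <- 1.5; T_s <- 10; fps <- 60
  x <- A * sin(2 * pi * f * seq(0, T_s - 1 / fps, by = 1 / fps))
  expect_equal(moving_distance(c(0, abs(diff(x)))), 4 * A * f * T_s,
               tolerance = 0.02)
  expect_error(moving_distance(c(1, NA)), "finite")
})

test_that("moving distance through the trajectory route matches the sinusoid form", {
  mesh <- toy_mesh(16)
  fps <- 60; T_s <- 5; A <- 0.2; f <- 1
  tt <- seq(0, T_s - 1 / fps, by = 1 / fps)
  traj <- static_trajectory(mesh, T = length(tt), fps = fps)
  idx <- mesh$region_map$perioral
  for (k in idx) traj$coords[, k, 1] <- traj$coords[, k, 1] + A * sin(2 * pi * f * tt)
  series <- region_motion_series(traj, "perioral", remove_rigid = FALSE)
  expect_equal(moving_distance(series), 4 * A * f * T_s, tolerance = 0.02)
})

test_that("channel decomposition separates head and facial-muscle motion", {
  mesh <- toy_mesh(48)
  static <- static_trajectory(mesh, T = 30)
  ch0 <- compute_channels(static)
  for (s in ch0$channels) expect_lt(max(abs(s)), 1e-12)
  # head-only motion: head tracks overall, muscle channels silent
  head_only <- generate_actor_motion(
    mesh, actor_motion_params(blink_amp = 0, mouth_amp = 0, noise_sd = 0),
    4, 30, seed = 3
  )
  ch1 <- compute_channels(head_only)
  expect_gt(moving_distance(ch1$channels$head), 0.01)
  expect_gt(moving_distance(ch1$channels$overall), 0.01)
  expect_lt(moving_distance(ch1$channels$perioral), 1e-4)
  expect_lt(moving_distance(ch1$channels$left_periocular), 1e-4)
  # mouth-only motion: perioral active, head silent
  mouth_only <- generate_actor_motion(
    mesh, actor_motion_params(head_rot_amp = 0, head_trans_amp = 0,
                              blink_amp = 0, noise_sd = 0),
    4, 30, seed = 3
  )
  ch2 <- compute_channels(mouth_only)
  expect_gt(moving_distance(ch2$channels$perioral), 0.001)
  expect_lt(moving_distance(ch2$channels$head), 1e-8)
  expect_lt(moving_distance(ch2$channels$left_periocular), 1e-8)
})

test_that("region series are invariant to a global rigid transform of the scene", {
  mesh <- toy_mesh(32)
  traj <- generate_actor_motion(mesh, actor_motion_params(noise_sd = 0),
                                3, 30, seed = 12)
  moved <- transform_trajectory(traj, R = rot_axis(c(0, 1, 1), 0.6),
                                trans = c(1, -2, 0.5))
  for (region in c("left_periocular", "perioral")) {
    expect_equal(region_motion_series(moved, region),
                 region_motion_series(traj, region), tolerance = 1e-6)
  }
  expect_equal(head_motion_series(moved), head_motion_series(traj),
               tolerance = 1e-6)
})

test_that("all magnitudes scale linearly with the coordinate scale", {
  mesh <- toy_mesh(32)
  traj <- generate_actor_motion(mesh, actor_motion_params(), 3, 30, seed = 4)
  scaled <- traj
  scaled$coords <- traj$coords * 3
  scaled$mesh$coords <- mesh$coords * 3
  ch <- compute_channels(traj); ch3 <- compute_channels(scaled)
  for (nm in names(ch$channels)) {
    expect_equal(ch3$channels[[nm]], 3 * ch$channels[[nm]], tolerance = 1e-8)
  }
})

test_that("moving distance is additive over concatenated segments", {
  set.seed(2)
  s1 <- abs(rnorm(50)); s2 <- abs(rnorm(30))
  expect_equal(moving_distance(c(s1, s2)),
               moving_distance(s1) + moving_distance(s2))
})
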