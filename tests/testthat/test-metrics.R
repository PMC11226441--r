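test_that("smoothing and z-normalization have their hand-computed forms", {
  # constant series: zero-variance guard
  expect_equal(smooth_and_zscore(rep(3.2, 50), 0.5, 30), rep(0, 50))
  # window 0: plain z-score
  set.seed(1)
  x <- rnorm(40)
  expect_equal(smooth_and_zscore(x, 0, 30), (x - mean(x)) / sd(x),
               tolerance = 1e-12)
  # unit impulse, 3-frame window (0.1 s at 30 fps): hand convolution
  imp <- c(0, 0, 0, 0, 1, 0, 0, 0, 0)
  sm_expected <- c(0, 0, 0, 1 / 3, 1 / 3, 1 / 3, 0, 0, 0)
  z_expected <- (sm_expected - mean(sm_expected)) / sd(sm_expected)
  expect_equal(smooth_and_zscore(imp, 0.1, 30), z_expected, tolerance = 1e-12)
  expect_error(smooth_and_zscore(c(1, 2), 10, 30), "shorter")
})

test_that("peak detection matches hand-enumerated fixtures", {
  # flat series: no peaks
  expect_equal(nrow(detect_peaks(rep(0, 100))), 0)
  # two unit triangular bumps 2 s apart at 30 fps, threshold 0.5, sep 1 s
  tri <- function(center, half, n) pmax(0, 1 - abs(seq_len(n) - center) / half)
  x <- tri(31, 8, 120) + tri(91, 8, 120)
  pk <- detect_peaks(x, min_prominence = 0.5, min_separation_s = 1, fps = 30)
  expect_equal(pk$index, c(31, 91))
  expect_equal(pk$prominence, c(1, 1))
  # bump below threshold: nothing
  expect_equal(nrow(detect_peaks(0.3 * tri(31, 8, 120), min_prominence = 0.5)), 0)
  # conflict resolution: two peaks closer than the separation keep the higher
  y <- tri(30, 4, 90) + 0.8 * tri(42, 4, 90)
  pk2 <- detect_peaks(y, min_prominence = 0.3, min_separation_s = 0.5, fps = 30)
  expect_equal(pk2$index, 30)
  # equal heights: the tie goes to the earlier peak
  y2 <- tri(30, 4, 90) + tri(42, 4, 90)
  pk2b <- detect_peaks(y2, min_prominence = 0.3, min_separation_s = 0.5, fps = 30)
  expect_equal(pk2b$index, 30)
  # far enough apart, both survive
  pk2c <- detect_peaks(y, min_prominence = 0.3, min_separation_s = 0.3, fps = 30)
  expect_equal(pk2c$index, c(30, 42))
  # plateau: first index of the flat top is reported
  z <- c(0, 1, 2, 2, 2, 1, 0)
  pk3 <- detect_peaks(z, min_prominence = 1, min_separation_s = 0, fps = 30)
  expect_equal(pk3$index, 3)
})

test_that("raising the prominence threshold never adds peaks", {
  set.seed(5)
  x <- smooth_and_zscore(abs(rnorm(300)), 0.2, 30)
  counts <- sapply(c(0.2, 0.5, 1, 1.5, 2.5), function(p) {
    nrow(detect_peaks(x, min_prominence = p, min_separation_s = 0.1, fps = 30))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("diversity index reproduces hand-enumerated switch sequences", {
  fps <- 30; T <- 1800 # 60-s trial
  bump <- function(centers, n = T, half = 6) {
    Reduce(`+`, lapply(centers, function(cc) pmax(0, 1 - abs(seq_len(n) - cc) / half)))
  }
  flat <- rep(0, T)
  # alternating head / perioral peaks: [head, perioral, head, perioral]
  channels <- list(
    overall = flat, head = bump(c(300, 900)), periocular = flat,
    perioral = bump(c(600, 1200))
  )
  d <- diversity_index(channels, fps = fps, duration_s = 60)
  expect_equal(d$switch_count, 3L)
  expect_equal(d$index, 3)
  expect_equal(d$peaks$channel, c("head", "perioral", "head", "perioral"))
  # all channels flat: index 0
  d0 <- diversity_index(list(overall = flat, head = flat, periocular = flat,
                             perioral = flat), fps = fps, duration_s = 60)
  expect_equal(d0$switch_count, 0L)
  expect_equal(d0$index, 0)
  # five peaks all from one channel: no switches
  d1 <- diversity_index(list(overall = flat,
                             head = bump(c(200, 500, 800, 1100, 1400)),
                             periocular = flat, perioral = flat),
                        fps = fps, duration_s = 60)
  expect_equal(nrow(d1$peaks), 5)
  expect_equal(d1$index, 0)
  # simultaneous peaks break ties by the fixed channel order
  d2 <- diversity_index(list(overall = flat, head = bump(600),
                             periocular = bump(600), perioral = flat),
                        fps = fps, duration_s = 60)
  expect_equal(d2$peaks$channel, c("head", "periocular"))
})

test_that("diversity index pools the periocular sides and is scale invariant", {
  fps <- 30; T <- 600
  bump <- function(cc, n = T) pmax(0, 1 - abs(seq_len(n) - cc) / 6)
  channels <- list(overall = rep(0, T), head = bump(100),
                   left_periocular = bump(300), right_periocular = bump(300),
                   perioral = bump(500))
  d <- diversity_index(channels, fps = fps, duration_s = 20)
  expect_equal(d$peaks$channel, c("head", "periocular", "perioral"))
  expect_equal(d$switch_count, 2L)
  expect_equal(d$index, 2 / (20 / 60))
  scaled <- lapply(channels, function(x) 40 * x)
  expect_equal(diversity_index(scaled, fps = fps, duration_s = 20)$index, d$index)
  expect_error(diversity_index(list(overall = rep(0, T)), fps = fps,
                               duration_s = 20), "periocular")
})

test_that("latency estimation finds constructed delays and survives noise", {
  set.seed(3)
  x <- abs(rnorm(300))
  delayed <- c(rep(x[1], 9), x[1:291])
  expect_equal(estimate_latency(x, delayed, 0.5, 30), 9L)
  expect_equal(estimate_latency(x, x, 0.5, 30), 0L)
  expect_warning(z <- estimate_latency(rep(1, 100), rep(2, 100), 0.5, 30),
                 "zero-variance")
  expect_equal(z, 0L)
  # Monte-Carlo: delayed + noise at SNR 10, recovered in >= 95% of 100 seeds
  hits <- sapply(1:100, function(s) {
    set.seed(s)
    sig <- abs(rnorm(300))
    shown <- c(rep(sig[1], 9), sig[1:291]) + rnorm(300, sd = sd(sig) / sqrt(10))
    estimate_latency(sig, shown, 0.5, 30) == 9L
  })
  expect_gte(mean(hits), 0.95)
})

test_that("motion error is zero under full control and follows the mixing algebra", {
  mesh <- toy_mesh(32)
  p1 <- generate_actor_motion(mesh, actor_motion_params(noise_sd = 0), 3, 30,
                              seed = 21)
  p2 <- generate_actor_motion(mesh, actor_motion_params(noise_sd = 0), 3, 30,
                              seed = 22)
  d1 <- displacement_field(p1); d2 <- displacement_field(p2)
  # full control, zero latency: exact zero error
  shown_full <- render_displayed(mesh, d1, mixing_config(w = 1, latency_frames = 0))
  err_full <- motion_error(p1, shown_full)
  expect_equal(err_full$mean_error, 0, tolerance = 1e-12)
  expect_equal(err_full$latency_est_frames, 0L)
  # 50/50 mixing: error equals half the mean RMS difference of the actors
  shown_half <- render_displayed(mesh, mix_displacements(d1, d2, 0.5),
                                 mixing_config(w = 0.5, latency_frames = 0))
  err_half <- motion_error(p1, shown_half)
  diff_d <- d1 - d2
  rms_t <- sqrt(rowMeans(matrix(diff_d[, , 1]^2 + diff_d[, , 2]^2 +
                                  diff_d[, , 3]^2, dim(diff_d)[1])))
  expect_equal(err_half$mean_error, 0.5 * mean(rms_t), tolerance = 1e-6)
  # partial control errs more than full control whenever the other moves
  expect_gt(err_half$mean_error, err_full$mean_error)
  # latency compensation recovers the configured 9-frame delay
  shown_lag <- render_displayed(mesh, d1, mixing_config(w = 1, latency_frames = 9))
  err_lag <- motion_error(p1, shown_lag)
  expect_equal(err_lag$latency_est_frames, 9L)
  expect_lt(err_lag$mean_error, 0.05 * err_half$mean_error + 1e-4)
})

test_that("motion error is non-increasing as control weight rises", {
  mesh <- toy_mesh(24)
  p1 <- generate_actor_motion(mesh, actor_motion_params(noise_sd = 0), 2, 30,
                              seed = 31)
  p2 <- generate_actor_motion(mesh, actor_motion_params(noise_sd = 0), 2, 30,
                              seed = 32)
  d1 <- displacement_field(p1); d2 <- displacement_field(p2)
  errs <- sapply(c(0.3, 0.5, 0.7, 0.9, 1), function(w) {
    shown <- render_displayed(mesh, mix_displacements(d1, d2, w),
                              mixing_config(w = w, latency_frames = 0))
    motion_error(p1, shown)$mean_error
  })
  expect_true(all(diff(errs) <= 1e-10))
})
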