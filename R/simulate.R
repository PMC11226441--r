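#' Actor motion parameters
#'
#' Parametrizes the synthetic motion of one actor in front of a webcam:
#' rigid head pose (rotation and translation), blinking, mouth movement,
#' dominant-channel switching and landmark jitter. All coordinates are
#' dimensionless mesh units (the face spans roughly \[-1, 1\]).
#'
#' Each continuous component is a mixture of a low-frequency sinusoid and
#' a smooth first-order autoregressive random walk (weight `ar_weight`),
#' so free movement is neither pure noise nor a pure tone. A
#' dominant-channel schedule switches emphasis among head, eye and mouth
#' activity at an expected `switch_rate` switches per minute: the dominant
#' channel's amplitude is boosted and the others damped, which is what the
#' peak-switching diversity index later picks up. `exploration_multiplier`
#' scales every motion amplitude jointly; exploratory behaviour is
#' modelled as a larger multiplier *and* a higher `switch_rate`.
#'
#' @param head_rot_amp Length-3 rotation amplitudes (radians; pitch, yaw, roll).
#' @param head_rot_freq Length-3 rotation frequencies (Hz).
#' @param head_trans_amp Length-3 translation amplitudes (mesh units).
#' @param head_trans_freq Length-3 translation frequencies (Hz).
#' @param blink_rate Blink events per second.
#' @param blink_amp Eyelid displacement amplitude (mesh units).
#' @param blink_dur_s Blink duration in seconds.
#' @param mouth_amp Mouth displacement amplitude (mesh units).
#' @param mouth_freq Mouth oscillation frequency (Hz).
#' @param exploration_multiplier Scalar `>= 0` scaling all amplitudes.
#' @param action_rate Scalar `>= 0` multiplying every episode rate (head
#'   actions, blinks, mouth gestures): exploratory behaviour is not only
#'   larger but also more frequent.
#' @param switch_rate Expected dominant-channel switches per minute.
#' @param noise_sd Per-landmark, per-frame tracking-jitter SD (mesh units);
#'   not scaled by `exploration_multiplier` (it emulates measurement
#'   noise, not behaviour).
#' @param ar_weight Weight in `[0, 1]` of the autoregressive component
#'   relative to the sinusoid (0 = deterministic sinusoids).
#' @param ar_tau_s Autocorrelation time of the AR component (seconds).
#' @return An object of class `actor_motion_params`.
#' @export
actor_motion_params <- function(head_rot_amp = c(0.15, 0.20, 0.08),
                                head_rot_freq = c(0.23, 0.31, 0.17),
                                head_trans_amp = c(0.12, 0.10, 0.05),
                                head_trans_freq = c(0.27, 0.21, 0.13),
                                blink_rate = 0.18,
                                blink_amp = 0.06,
                                blink_dur_s = 0.15,
                                mouth_amp = 0.08,
                                mouth_freq = 0.9,
                                exploration_multiplier = 1,
                                action_rate = 1,
                                switch_rate = 5,
                                noise_sd = 0.002,
                                ar_weight = 0.4,
                                ar_tau_s = 1.5) {
  p <- list(
    head_rot_amp = rep_len(head_rot_amp, 3), head_rot_freq = rep_len(head_rot_freq, 3),
    head_trans_amp = rep_len(head_trans_amp, 3), head_trans_freq = rep_len(head_trans_freq, 3),
    blink_rate = blink_rate, blink_amp = blink_amp, blink_dur_s = blink_dur_s,
    mouth_amp = mouth_amp, mouth_freq = mouth_freq,
    exploration_multiplier = exploration_multiplier, action_rate = action_rate,
    switch_rate = switch_rate,
    noise_sd = noise_sd, ar_weight = ar_weight, ar_tau_s = ar_tau_s
  )
  for (nm in c("head_rot_amp", "head_trans_amp", "blink_rate", "blink_amp",
               "mouth_amp", "exploration_multiplier", "action_rate",
               "switch_rate", "noise_sd")) {
    if (any(!is.finite(p[[nm]])) || any(p[[nm]] < 0)) {
      stopf("`%s` must be non-negative and finite", nm)
    }
  }
  check_number(p$ar_weight, "ar_weight", 0, 1)
  check_number(p$ar_tau_s, "ar_tau_s", lower = 1e-6)
  check_number(p$blink_dur_s, "blink_dur_s", lower = 1e-6)
  structure(p, class = "actor_motion_params")
}

#' Default exploration-mode actor parameters
#'
#' Convenience preset for the other-face (exploration) condition: same
#' baseline as [actor_motion_params()] but with all amplitudes scaled by
#' 1.6, action-episode rates scaled by 2, and dominant-channel
#' switching raised from 5 to 12 per minute.
#'
#' @param ... Overrides passed to [actor_motion_params()].
#' @export
exploration_motion_params <- function(...) {
  actor_motion_params(exploration_multiplier = 1.6, action_rate = 2,
                      switch_rate = 12, ...)
}

# Unit-variance smooth AR(1) series of length T.
ar1_series <- function(T, fps, tau_s) {
  rho <- exp(-1 / (fps * tau_s))
  innov <- rnorm(T) * sqrt(1 - rho^2)
  innov[1] <- rnorm(1)
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

# Sinusoid + AR(1) mixture with unit nominal amplitude.
component_series <- function(T, fps, freq, ar_weight, tau_s) {
  tt <- (seq_len(T) - 1) / fps
  phase <- runif(1, 0, 2 * pi)
  (1 - ar_weight) * sin(2 * pi * freq * tt + phase) +
    ar_weight * ar1_series(T, fps, tau_s)
}

# Dominant-channel schedule: per-frame label in {1 = head, 2 = eyes,
# 3 = mouth}, changing at exponential waiting times with an expected
# `switch_rate` dominance changes per minute. 0 disables dominance (all
# channels equally active).
dominance_schedule <- function(T, fps, switch_rate) {
  if (switch_rate <= 0) return(rep(0L, T))
  rate_per_frame <- switch_rate / 60 / fps
  dominant <- integer(T)
  cur <- sample.int(3, 1)
  t <- 1L
  while (t <= T) {
    gap <- max(1L, ceiling(rexp(1, rate_per_frame)))
    upper <- min(T, t + gap - 1L)
    dominant[t:upper] <- cur
    cur <- sample(setdiff(1:3, cur), 1)
    t <- upper + 1L
  }
  dominant
}

# Episode-rate multiplier for one channel under the dominance schedule:
# the dominant channel initiates actions more often, the others rarely.
rate_multiplier <- function(schedule, channel, boost = 2.5, damp = 0.15) {
  if (all(schedule == 0L)) return(rep(1, length(schedule)))
  ifelse(schedule == channel, boost, damp)
}

# Event times of an inhomogeneous Poisson process with base rate
# `base_rate` (events/s) modulated by the per-frame multiplier, via
# thinning of a homogeneous process at the maximum rate. The number and
# order of RNG draws do not depend on any amplitude parameter.
episode_times <- function(T, fps, base_rate, rate_mult, min_events = 0L,
                          refractory_s = 1) {
  dur <- T / fps
  rmax <- base_rate * max(rate_mult)
  times <- numeric(0)
  if (rmax > 0) {
    times <- cumsum(rexp(ceiling(rmax * dur * 3) + 20, rmax))
    times <- times[times < dur]
    if (length(times)) {
      frame <- pmin(T, floor(times * fps) + 1L)
      times <- times[runif(length(times)) < base_rate * rate_mult[frame] / rmax]
    }
  }
  # physiological floor: some actions (e.g. blinks) happen regardless of
  # what the actor is concentrating on
  if (length(times) < min_events) {
    times <- sort(c(times, runif(min_events - length(times), 0, dur)))
  }
  # refractory period: an action occupies the effectors for a while, so
  # episodes of one channel cannot pile on top of each other
  if (length(times) > 1L && refractory_s > 0) {
    kept <- times[1]
    for (tt in times[-1]) if (tt - kept[length(kept)] >= refractory_s) kept <- c(kept, tt)
    times <- kept
  }
  times
}

# Sum of raised-cosine (Hann) bumps of width `dur_s` centered at `times`.
bump_envelope <- function(T, fps, times, dur_s, weights = NULL) {
  env <- numeric(T)
  if (!length(times)) return(env)
  if (is.null(weights)) weights <- rep(1, length(times))
  half <- max(1L, round(dur_s * fps / 2))
  for (e in seq_along(times)) {
    center <- round(times[e] * fps) + 1L
    span <- max(1L, center - half):min(T, center + half)
    env[span] <- env[span] +
      weights[e] * 0.5 * (1 + cos(pi * (span - center) / half))
  }
  env
}

# Centered moving average with shrinking windows at the edges.
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  half <- (w - 1) %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Generate one actor's landmark motion
#'
#' Simulates `duration_s` seconds of webcam-style facial motion on a
#' neutral mesh: rigid head pose applied to all landmarks, blink
#' deformations confined to the periocular regions and mouth deformations
#' confined to the perioral region (both defined in the head-local frame,
#' so they ride on the head motion), plus optional white tracking jitter.
#' All stochastic draws are made at unit scale and then multiplied by
#' their amplitudes, so trajectories are identical under the same seed
#' regardless of amplitude settings, and non-rigid path length scales
#' linearly with the amplitudes.
#'
#' @param mesh A [neutral_mesh][make_neutral_mesh].
#' @param params An [actor_motion_params()].
#' @param duration_s Trial duration in seconds (default 20).
#' @param fps Frames per second (default 30).
#' @param seed Integer seed; the same seed reproduces the trajectory exactly.
#' @return A [landmark_trajectory()].
#' @export
generate_actor_motion <- function(mesh, params, duration_s = 20, fps = 30,
                                  seed = 1L) {
  validate_mesh(mesh)
  stopifnot(inherits(params, "actor_motion_params"))
  check_number(duration_s, "duration_s", lower = 2 / fps)
  check_number(fps, "fps", lower = 1e-9)
  if (any(c(params$head_rot_freq, params$head_trans_freq, params$mouth_freq) >= fps / 2)) {
    stopf("motion frequencies must stay below the Nyquist limit fps/2 = %g", fps / 2)
  }
  T <- round(duration_s * fps)
  mult <- params$exploration_multiplier
  rm <- mesh$region_map
  centroid <- colMeans(mesh$coords)
  base <- sweep(mesh$coords, 2, centroid)

  with_seed(seed, {
    sched <- dominance_schedule(T, fps, params$switch_rate)

    # Rigid head motion: a small continuous postural wander plus episodic
    # head actions (turns/nods) whose rate follows the dominance schedule.
    head_times <- episode_times(T, fps, 0.12 * params$action_rate,
                                rate_multiplier(sched, 1L), min_events = 2L)
    head_dirs <- matrix(rnorm(6 * length(head_times)), nrow = 6)
    freqs <- c(params$head_rot_freq, params$head_trans_freq)
    wander <- vapply(seq_len(6), function(i) {
      component_series(T, fps, freqs[i], params$ar_weight, params$ar_tau_s)
    }, numeric(T))
    bursts <- vapply(seq_len(6), function(i) {
      bump_envelope(T, fps, head_times, 0.8, head_dirs[i, ])
    }, numeric(T))
    sig <- 0.15 * wander + bursts
    angles <- sig[, 1:3] * rep(params$head_rot_amp, each = T) * mult
    trans <- sig[, 4:6] * rep(params$head_trans_amp, each = T) * mult

    # Non-rigid deformation field in the head-local frame, built only on
    # the deforming landmark rows. Eye and mouth activity is episodic
    # (blinks, mouth gestures), so channel peaks mark discrete actions.
    def_idx <- c(rm$left_periocular, rm$right_periocular, rm$perioral)
    deform <- array(0, dim = c(T, length(def_idx), 3))
    eye_times <- episode_times(T, fps, params$blink_rate * params$action_rate,
                               rate_multiplier(sched, 2L), min_events = 2L)
    blink_env <- bump_envelope(T, fps, eye_times, params$blink_dur_s * 2)
    eye_sig <- blink_env * params$blink_amp * mult
    for (region in c("left_periocular", "right_periocular")) {
      loc <- match(rm[[region]], def_idx)
      w <- seq(0.5, 1, length.out = length(loc))
      deform[, loc, 2] <- deform[, loc, 2] - outer(eye_sig, w)
    }
    mouth_times <- episode_times(T, fps, 0.12 * params$action_rate,
                                 rate_multiplier(sched, 3L), min_events = 2L)
    mouth_wts <- runif(length(mouth_times), 0.6, 1.3)
    mouth_env <- bump_envelope(T, fps, mouth_times, 0.8, mouth_wts)
    tt <- (seq_len(T) - 1) / fps
    gesture <- sin(2 * pi * 2.2 * tt + runif(1, 0, 2 * pi))
    mouth_sig <- mouth_env * gesture * params$mouth_amp * mult
    loc <- match(rm$perioral, def_idx)
    w <- seq(-1, 1, length.out = length(loc))
    deform[, loc, 2] <- deform[, loc, 2] + outer(mouth_sig, w)

    R <- euler_rotations_cpp(angles)
    coords <- from_cube(apply_pose_cpp(base, R, trans))
    if (any(eye_sig != 0) || any(mouth_sig != 0)) {
      coords[, def_idx, ] <- coords[, def_idx, ] +
        from_cube(rotate_fields_cpp(as_cube(deform), R))
    }
    coords <- sweep_frames(coords, matrix(centroid, mesh$K, 3, byrow = TRUE), `+`)
    if (params$noise_sd > 0) {
      coords <- coords + array(rnorm(length(coords), sd = params$noise_sd),
                               dim = dim(coords))
    }
    landmark_trajectory(coords, fps = fps, mesh = mesh,
                        meta = list(seed = seed, params = params))
  })
}

#' Experiment design
#'
#' The within-participant 2 x 2 design of the face-motion mixing study:
#' each participant completes `reps` repetitions of every
#' face (self/other) x control (full/partial) condition, each trial
#' lasting `trial_duration_s` seconds at `fps` frames/s. Defaults are the
#' study's: 20 participants, 5 repetitions, 20-s trials at 30 fps.
#'
#' @param n_participants Number of participants.
#' @param reps Repetitions per condition.
#' @param trial_duration_s Trial length in seconds.
#' @param fps Frames per second.
#' @param seed Master seed for the whole experiment.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(n_participants = 20L, reps = 5L,
                              trial_duration_s = 20, fps = 30, seed = 1L) {
  n_participants <- check_count(n_participants, "n_participants")
  reps <- check_count(reps, "reps")
  check_number(trial_duration_s, "trial_duration_s", lower = 1e-9)
  check_number(fps, "fps", lower = 1e-9)
  if (abs(trial_duration_s * fps - round(trial_duration_s * fps)) > 1e-9) {
    stopf("trial_duration_s x fps must be an integer frame count")
  }
  structure(
    list(n_participants = n_participants, faces = c("self", "other"),
         controls = c("full", "partial"), reps = reps,
         trial_duration_s = trial_duration_s, fps = fps,
         seed = as.integer(seed)),
    class = "experiment_design"
  )
}
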