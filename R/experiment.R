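#' Generate a full synthetic face-motion mixing experiment
#'
#' Simulates the complete 2 x 2 within-participant study: every
#' participant x face x control x repetition trial gets
#'
#' 1. a participant ("driving") trajectory generated with the
#'    face-dependent actor parameters (`self_params` for the self-face,
#'    exploratory `other_params` for the other-face — larger and more
#'    channel-switching motion);
#' 2. for partial-control trials, an independent experimenter trajectory;
#' 3. a displayed trajectory rendered from the convex displacement mix
#'    (`w = 1` full, `w = 0.5` partial) on the target identity's mesh,
#'    behind the configured display latency;
#' 4. the objective control measures ([motion_error()], estimated
#'    latency) and a sensorimotor-consistency value
#'    `c = clip(1 - normalized error - residual_discrepancy)`, where the
#'    residual term models the technical imperfection of the display that
#'    keeps even full control below perfect consistency;
#' 5. agency ratings from the two-mode curve model
#'    ([simulate_ratings()]) and identification ratings from
#'    [identification_model()];
#' 6. optionally (default) the kinematic moving distances and the
#'    peak-switching diversity index of the participant's own motion.
#'
#' Participant heterogeneity is modelled by per-participant lognormal
#' multipliers on motion amplitude and switch rate, a small normal jitter
#' on the curve midpoints, and a random rating intercept. All randomness
#' descends deterministically from the design's master seed.
#'
#' @param design An [experiment_design()].
#' @param self_params,other_params [actor_motion_params()] for the
#'   self-face (exploitation) and other-face (exploration) conditions.
#' @param curve_params Two-mode curve list as [default_curve_params()].
#' @param experimenter_params Actor parameters of the experimenter's
#'   motion in partial-control trials.
#' @param mixing A [mixing_config()]; its `w` is used for partial trials
#'   (full trials always use `w = 1`) and its latency for all trials.
#' @param rating_noise_sd Agency/identification rating noise SD.
#' @param id_coeffs Coefficients for [identification_model()].
#' @param residual_discrepancy Consistency lost to display imperfection
#'   even under full control (default 0.18).
#' @param mesh The shared topology ([make_neutral_mesh()]); per-identity
#'   meshes are small deterministic perturbations of it.
#' @param compute_metrics Compute per-trial kinematic metrics (moving
#'   distances, diversity index)? Default `TRUE`.
#' @param keep_trajectories Keep the generated trajectories in the result
#'   (memory-heavy; default `FALSE`).
#' @param seed Master seed (defaults to `design$seed`).
#' @return A list of class `agencymix_experiment` with elements `trials`
#'   (the trial tibble), `design`, and `trajectories` (named list or
#'   `NULL`).
#' @export
generate_experiment <- function(design = experiment_design(),
                                self_params = actor_motion_params(),
                                other_params = exploration_motion_params(),
                                curve_params = default_curve_params(),
                                experimenter_params = actor_motion_params(
                                  exploration_multiplier = 1.2, switch_rate = 8
                                ),
                                mixing = mixing_config(),
                                rating_noise_sd = 10,
                                id_coeffs = c(intercept = 20, beta_self = 45,
                                              beta_control = 12),
                                residual_discrepancy = 0.18,
                                mesh = make_neutral_mesh("toy", 64L),
                                compute_metrics = TRUE,
                                keep_trajectories = FALSE,
                                seed = design$seed) {
  stopifnot(inherits(design, "experiment_design"))
  check_number(residual_discrepancy, "residual_discrepancy", 0, 1)
  validate_mesh(mesh)
  fps <- design$fps
  dur <- design$trial_duration_s

  grid <- tidyr::expand_grid(
    participant = sprintf("P%02d", seq_len(design$n_participants)),
    face = design$faces, control = design$controls,
    repetition = seq_len(design$reps)
  )

  # per-identity meshes: shared topology, small deterministic shape offsets
  identity_mesh <- function(id) {
    m <- mesh
    m$coords <- mesh$coords + with_seed(
      derive_seed(seed, "identity", id),
      matrix(rnorm(length(mesh$coords), sd = 0.02), nrow = mesh$K)
    )
    m
  }
  other_mesh <- identity_mesh("experimenter")

  # per-participant modifiers
  participants <- unique(grid$participant)
  mods <- with_seed(derive_seed(seed, "participants"), tibble::tibble(
    participant = participants,
    amp_mult = exp(rnorm(length(participants), 0, 0.12)),
    switch_mult = exp(rnorm(length(participants), 0, 0.15)),
    c0_jitter = rnorm(length(participants), 0, 0.04),
    intercept_shift = rnorm(length(participants), 0, 5)
  ))

  scale_params <- function(p, amp_mult, switch_mult) {
    p$exploration_multiplier <- p$exploration_multiplier * amp_mult
    p$switch_rate <- p$switch_rate * switch_mult
    p
  }

  store <- if (keep_trajectories) list() else NULL
  trial_rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    mod <- mods[mods$participant == g$participant, ]
    p_mesh <- identity_mesh(g$participant)
    act <- if (g$face == "self") self_params else other_params
    act <- scale_params(act, mod$amp_mult, mod$switch_mult)
    trial_key <- paste(g$participant, g$face, g$control, g$repetition, sep = "_")
    driving <- generate_actor_motion(
      p_mesh, act, dur, fps, seed = derive_seed(seed, trial_key, "driving")
    )
    disp_p <- displacement_field(driving)
    w <- if (g$control == "full") 1 else mixing$w
    if (g$control == "partial") {
      exper <- generate_actor_motion(
        other_mesh, experimenter_params, dur, fps,
        seed = derive_seed(seed, trial_key, "experimenter")
      )
      mixed <- mix_displacements(disp_p, displacement_field(exper), w,
                                 renormalize = mixing$renormalize)
    } else {
      mixed <- disp_p
    }
    target_mesh <- if (g$face == "self") p_mesh else other_mesh
    displayed <- render_displayed(target_mesh, mixed, mixing, fps = fps,
                                  meta = list(trial_id = trial_key))
    ch <- if (compute_metrics) compute_channels(driving) else NULL
    ov_d <- if (is.null(ch)) {
      as.numeric(mean_step_cpp(as_cube(driving$coords)))
    } else {
      ch$channels$overall
    }
    disp_shown <- displacement_field(displayed)
    err <- motion_error_core(
      disp_p, disp_shown, ov_d,
      as.numeric(mean_step_cpp(as_cube(displayed$coords))),
      fps, max_lag_s = 0.5
    )
    scale_ref <- mean_disp_magnitude(disp_p) + mean_disp_magnitude(disp_shown)
    e_norm <- if (scale_ref > 1e-12) err$mean_error / scale_ref else 0
    consistency <- min(1, max(0, 1 - e_norm - residual_discrepancy))

    row <- list(
      participant = g$participant, face = g$face, control = g$control,
      repetition = g$repetition, consistency = consistency,
      motion_error = err$mean_error, latency_est = err$latency_est_frames
    )
    if (compute_metrics) {
      div <- diversity_index(ch)
      row <- c(row, list(
        dist_overall = moving_distance(ch$channels$overall),
        dist_head = moving_distance(ch$channels$head),
        dist_eye_l = moving_distance(ch$channels$left_periocular),
        dist_eye_r = moving_distance(ch$channels$right_periocular),
        dist_lip = moving_distance(ch$channels$perioral),
        diversity = div$index
      ))
    }
    trial_rows[[i]] <- row
    if (keep_trajectories) {
      store[[trial_key]] <- list(driving = driving, displayed = displayed)
    }
  }
  trials <- dplyr::bind_rows(lapply(trial_rows, tibble::as_tibble))

  # mode-dependent curves with per-participant midpoint jitter
  jitter_curves <- function(pars, jit) {
    lapply(pars, function(p) {
      p$c0 <- min(1 - 1e-6, max(1e-6, p$c0 + jit))
      p
    })
  }
  agency <- numeric(nrow(trials))
  for (pid in participants) {
    sel <- trials$participant == pid
    mod <- mods[mods$participant == pid, ]
    agency[sel] <- simulate_ratings(
      trials$consistency[sel], trials$face[sel],
      params_by_mode = jitter_curves(curve_params, mod$c0_jitter),
      noise_sd = rating_noise_sd,
      seed = derive_seed(seed, "agency", pid)
    )
    agency[sel] <- pmin(100, pmax(0, agency[sel] + mod$intercept_shift))
  }
  trials$agency <- agency
  trials$identification <- identification_model(
    trials$face, trials$control, coeffs = id_coeffs,
    noise_sd = rating_noise_sd, seed = derive_seed(seed, "identification")
  )
  trials <- dplyr::relocate(trials, "agency", "identification",
                            .after = "repetition")
  structure(list(trials = trials, design = design, trajectories = store),
            class = "agencymix_experiment")
}

mean_disp_magnitude <- function(disp) {
  mean(sqrt(disp[, , 1]^2 + disp[, , 2]^2 + disp[, , 3]^2))
}

#' @export
print.agencymix_experiment <- function(x, ...) {
  d <- x$design
  cat(sprintf(
    "<agencymix_experiment> %d participants x 2 x 2 x %d reps = %d trials (%g s @ %g fps)\n",
    d$n_participants, d$reps, nrow(x$trials), d$trial_duration_s, d$fps))
  invisible(x)
}
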