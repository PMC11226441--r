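#' Smooth and z-normalize a motion channel
#'
#' Pre-processing for peak detection: a centered moving average of width
#' `window_s` seconds (shrinking windows at the trial edges) followed by
#' per-trial z-normalization. A constant series maps to all zeros
#' (zero-variance guard), and `window_s = 0` skips the smoothing.
#'
#' @param series Numeric per-frame magnitude series.
#' @param window_s Smoothing window in seconds (default 0.5).
#' @param fps Frames per second.
#' @return Numeric series of the same length.
#' @export
smooth_and_zscore <- function(series, window_s = 0.5, fps = 30) {
  check_number(window_s, "window_s", lower = 0)
  w <- max(1L, round(window_s * fps))
  if (w >= length(series)) stopf("smoothing window must be shorter than the series")
  sm <- moving_average(series, w)
  s <- stats::sd(sm)
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(series)))
  (sm - mean(sm)) / s
}

#' Detect prominent peaks in a normalized series
#'
#' Finds local maxima whose topographic prominence (height above the
#' higher of the two flanking saddles) reaches `min_prominence`, then
#' enforces a minimum temporal separation: when two candidates are closer
#' than `min_separation_s`, the higher one is kept (ties resolved in
#' favour of the earlier peak).
#'
#' @param series Numeric series (typically the output of
#'   [smooth_and_zscore()], so heights and prominences are in z-units).
#' @param min_prominence Minimum prominence (z-units), `> 0`.
#' @param min_separation_s Minimum separation between kept peaks (s).
#' @param fps Frames per second.
#' @param channel Optional channel label attached to the result.
#' @return A tibble with columns `index` (1-based frame), `time_s`,
#'   `height`, `prominence`, `channel`, ordered by time. May be empty.
#' @export
detect_peaks <- function(series, min_prominence = 1, min_separation_s = 0.3,
                         fps = 30, channel = NA_character_) {
  core <- find_peaks_core(series, min_prominence, min_separation_s, fps)
  tibble::tibble(
    index = core$index,
    time_s = (core$index - 1L) / fps,
    height = core$height,
    prominence = core$prominence,
    channel = rep(channel, length(core$index))
  )
}

find_peaks_core <- function(series, min_prominence, min_separation_s, fps) {
  check_number(min_prominence, "min_prominence", lower = 1e-12)
  check_number(min_separation_s, "min_separation_s", lower = 0)
  n <- length(series)
  empty <- list(index = integer(), height = numeric(), prominence = numeric())
  if (n < 3L) return(empty)
  # local maxima, plateau-aware: a rise followed (possibly after a flat
  # stretch) by a fall marks the first index of the plateau top
  dx <- diff(series)
  nz <- which(dx != 0)
  cand <- integer()
  if (length(nz) >= 2L) {
    s <- sign(dx[nz])
    chg <- which(s[-length(s)] > 0 & s[-1] < 0)
    cand <- nz[chg] + 1L
  }
  if (!length(cand)) return(empty)
  prom <- as.numeric(prominences_cpp(series, cand))
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(empty)
  # separation: greedily keep by descending height, earlier index on ties
  ord <- order(-series[cand], cand)
  min_gap <- min_separation_s * fps
  kept <- integer()
  for (i in ord) {
    if (!length(kept) || all(abs(cand[i] - cand[kept]) >= min_gap)) {
      kept <- c(kept, i)
    }
  }
  sel <- order(cand[kept])
  kept <- kept[sel]
  list(index = cand[kept], height = series[cand[kept]], prominence = prom[kept])
}

#' Parameters of the motion-diversity index
#'
#' @param window_s Smoothing window in seconds.
#' @param min_prominence Peak prominence threshold in z-units.
#' @param min_separation_s Minimum peak separation in seconds.
#' @param include_overall Keep the `overall` channel in the switching set
#'   (default `TRUE`); it is correlated with the others, and dropping it
#'   is offered as a sensitivity option.
#' @return A list of class `diversity_params`.
#' @export
diversity_params <- function(window_s = 0.5, min_prominence = 1,
                             min_separation_s = 0.3, include_overall = TRUE) {
  structure(list(window_s = window_s, min_prominence = min_prominence,
                 min_separation_s = min_separation_s,
                 include_overall = isTRUE(include_overall)),
            class = "diversity_params")
}

#' Peak-switching motion-diversity index
#'
#' Quantifies how varied a trial's movement strategy is: each motion
#' channel (`overall`, `head`, `periocular` = pooled left + right,
#' `perioral`) is smoothed, z-normalized and searched for prominent
#' peaks; all peaks are merged into one time-ordered sequence (time ties
#' broken by the fixed channel order overall < head < periocular <
#' perioral) and the index counts how often the peak-bearing channel
#' switches between consecutive peaks, expressed as switches per minute.
#' Trials with 0 or 1 total peaks have index 0.
#'
#' @param channel_set A [motion_channels][compute_channels] object, or a
#'   named list of equal-length series including `overall`, `head`,
#'   `perioral` and either `periocular` or both `left_periocular` and
#'   `right_periocular` (pooled by averaging), plus `fps`/`duration_s`
#'   when not a `motion_channels` object.
#' @param params A [diversity_params()].
#' @param fps,duration_s Required only when `channel_set` is a bare list
#'   of series.
#' @return An object of class `diversity_result`: list with `peaks`
#'   (tibble), `switch_count`, `index` (switches/minute) and `duration_s`.
#' @export
diversity_index <- function(channel_set, params = diversity_params(),
                            fps = NULL, duration_s = NULL) {
  if (inherits(channel_set, "motion_channels")) {
    fps <- channel_set$fps
    duration_s <- channel_set$duration_s
    channels <- channel_set$channels
  } else {
    channels <- channel_set
    if (is.null(fps) || is.null(duration_s)) {
      stopf("`fps` and `duration_s` are required for a bare channel list")
    }
  }
  if (!"periocular" %in% names(channels)) {
    if (!all(c("left_periocular", "right_periocular") %in% names(channels))) {
      stopf("channel set needs `periocular` or both `left_periocular` and `right_periocular`")
    }
    channels$periocular <- (channels$left_periocular + channels$right_periocular) / 2
  }
  order_names <- c("overall", "head", "periocular", "perioral")
  if (!params$include_overall) order_names <- setdiff(order_names, "overall")
  missing_ch <- setdiff(order_names, names(channels))
  if (length(missing_ch)) {
    stopf("channel set lacks: %s", paste(missing_ch, collapse = ", "))
  }
  idx <- integer(); hei <- prm <- numeric(); chn <- character()
  ordn <- integer()
  for (ci in seq_along(order_names)) {
    nm <- order_names[ci]
    z <- smooth_and_zscore(channels[[nm]], params$window_s, fps)
    core <- find_peaks_core(z, params$min_prominence, params$min_separation_s, fps)
    idx <- c(idx, core$index)
    hei <- c(hei, core$height)
    prm <- c(prm, core$prominence)
    chn <- c(chn, rep(nm, length(core$index)))
    ordn <- c(ordn, rep(ci, length(core$index)))
  }
  o <- order(idx, ordn)
  peaks <- tibble::tibble(
    index = idx[o], time_s = (idx[o] - 1L) / fps,
    height = hei[o], prominence = prm[o], channel = chn[o]
  )
  switch_count <- if (nrow(peaks) >= 2L) {
    sum(peaks$channel[-1] != peaks$channel[-nrow(peaks)])
  } else 0L
  structure(
    list(peaks = peaks, switch_count = as.integer(switch_count),
         index = switch_count / (duration_s / 60), duration_s = duration_s),
    class = "diversity_result"
  )
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("<diversity_result> %d peaks, %d switches over %.1f s -> %.2f switches/min\n",
              nrow(x$peaks), x$switch_count, x$duration_s, x$index))
  invisible(x)
}

#' Estimate the display latency between two motion series
#'
#' Argmax of the cross-correlation between the driving and displayed
#' overall-motion series over lags `0..max_lag_s * fps` frames; ties go
#' to the smallest lag. A zero-variance input yields lag 0 with a
#' warning.
#'
#' @param driving_overall,displayed_overall Equal-length numeric series.
#' @param max_lag_s Largest lag searched, in seconds.
#' @param fps Frames per second.
#' @return Integer lag in frames.
#' @export
estimate_latency <- function(driving_overall, displayed_overall,
                             max_lag_s = 0.5, fps = 30) {
  check_number(max_lag_s, "max_lag_s", lower = 0)
  n <- length(driving_overall)
  if (length(displayed_overall) != n) stopf("series must have equal length")
  max_lag <- min(n - 2L, floor(max_lag_s * fps))
  a <- driving_overall - mean(driving_overall)
  b <- displayed_overall - mean(displayed_overall)
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
    rlang::warn("zero-variance motion series; returning latency 0")
    return(0L)
  }
  cc <- vapply(0:max_lag, function(l) {
    sa <- a[seq_len(n - l)]
    sb <- b[seq_len(n - l) + l]
    sum(sa * sb) / (n - l)
  }, numeric(1))
  as.integer(which.max(cc) - 1L)
}

#' Motion error between driving and displayed trajectories
#'
#' The objective control measure: both trajectories are converted to
#' displacement-from-neutral fields, the display latency is estimated
#' from the overall-motion series and compensated, and the error is the
#' mean over frames of the RMS (over landmarks) difference between the
#' two displacement fields. Under full control with zero latency the
#' error is exactly 0; under 50/50 mixing with an independent second
#' actor it equals half the mean RMS difference between the two actors'
#' displacement fields.
#'
#' @param driving_traj The participant's own motion ([landmark_trajectory()]).
#' @param displayed_traj The displayed face's motion (same duration; the
#'   identity/mesh may differ but the topology must match).
#' @param max_lag_s Latency search window in seconds.
#' @return An object of class `control_error_result`: list with
#'   `latency_est_frames` and `mean_error`.
#' @export
motion_error <- function(driving_traj, displayed_traj, max_lag_s = 0.5) {
  stopifnot(inherits(driving_traj, "landmark_trajectory"),
            inherits(displayed_traj, "landmark_trajectory"))
  if (!identical(dim(driving_traj$coords), dim(displayed_traj$coords))) {
    stopf("driving and displayed trajectories disagree in shape")
  }
  dd <- displacement_field(driving_traj)
  ds <- displacement_field(displayed_traj)
  ov_d <- as.numeric(mean_step_cpp(as_cube(driving_traj$coords)))
  ov_s <- as.numeric(mean_step_cpp(as_cube(displayed_traj$coords)))
  motion_error_core(dd, ds, ov_d, ov_s, driving_traj$fps, max_lag_s)
}

motion_error_core <- function(dd, ds, ov_d, ov_s, fps, max_lag_s) {
  lag <- suppressWarnings(estimate_latency(ov_d, ov_s, max_lag_s, fps))
  T <- dim(dd)[1]
  span <- seq_len(T - lag)
  diff_field <- dd[span, , , drop = FALSE] - ds[span + lag, , , drop = FALSE]
  rms_t <- sqrt(rowMeans(matrix(
    diff_field[, , 1]^2 + diff_field[, , 2]^2 + diff_field[, , 3]^2,
    nrow = length(span)
  )))
  structure(list(latency_est_frames = lag, mean_error = mean(rms_t)),
            class = "control_error_result")
}

#' @export
print.control_error_result <- function(x, ...) {
  cat(sprintf("<control_error_result> latency %d frames, mean error %.4g\n",
              x$latency_est_frames, x$mean_error))
  invisible(x)
}
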