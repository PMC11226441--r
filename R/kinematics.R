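#' Least-squares rigid alignment of one frame onto a reference
#'
#' Finds the rotation `R` and translation `t` (no scaling) minimizing the
#' sum of squared distances between `reference_coords %*% t(R) + t` and
#' `frame_coords` over the landmarks in `index_set` — the classic
#' orthogonal-Procrustes/Kabsch solution via SVD of the cross-covariance,
#' with a reflection guard so `det(R) = +1`.
#'
#' @param frame_coords,reference_coords K x 3 coordinate matrices.
#' @param index_set Landmark indices to align on (default: all). Needs at
#'   least 3 non-collinear points.
#' @return A list with `rotation` (3 x 3), `translation` (length 3) and
#'   `residual` (RMS misfit over the index set).
#' @export
rigid_align <- function(frame_coords, reference_coords, index_set = NULL) {
  if (is.null(index_set)) index_set <- seq_len(nrow(reference_coords))
  if (length(index_set) < 3L) stopf("rigid alignment needs at least 3 points")
  F <- frame_coords[index_set, , drop = FALSE]
  G <- reference_coords[index_set, , drop = FALSE]
  cf <- colMeans(F); cg <- colMeans(G)
  Fc <- sweep(F, 2, cf); Gc <- sweep(G, 2, cg)
  sv_ref <- svd(Gc)$d
  if (sv_ref[2] < 1e-10 * max(sv_ref[1], 1e-300)) {
    stopf("degenerate (collinear) point set: rigid alignment is not unique",
          class = "agencymix_degenerate_error")
  }
  H <- crossprod(Gc, Fc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cf - as.numeric(R %*% cg)
  fit <- G %*% t(R) + matrix(trans, nrow(G), 3, byrow = TRUE)
  list(rotation = R, translation = trans,
       residual = sqrt(mean(rowSums((F - fit)^2))))
}

# Per-frame rigid head pose of a trajectory, estimated on the head_rigid
# region against the neutral mesh (policy "neutral") or the first frame
# (policy "first"). Returns rotation (3 x 3 x T) and translation (T x 3)
# arrays plus per-frame RMS residuals.
#' Estimate the rigid head-pose series of a trajectory
#'
#' @param traj A [landmark_trajectory()].
#' @param reference_frame_policy `"neutral"` (align against the neutral
#'   mesh) or `"first"` (against the first frame).
#' @return A list of class `rigid_pose_series` with elements `rotation`
#'   (3 x 3 x T), `translation` (T x 3) and `residual` (length T).
#' @export
rigid_pose_series <- function(traj, reference_frame_policy = c("neutral", "first")) {
  policy <- match.arg(reference_frame_policy)
  idx <- traj$mesh$region_map$head_rigid
  ref <- if (policy == "neutral") traj$mesh$coords else traj$coords[1, , ]
  # mirror rigid_align's degeneracy contract on the reference region
  sv <- svd(sweep(ref[idx, , drop = FALSE], 2, colMeans(ref[idx, , drop = FALSE])))$d
  if (length(idx) < 3L || sv[2] < 1e-10 * max(sv[1], 1e-300)) {
    stopf("head_rigid region is degenerate; cannot estimate head pose",
          class = "agencymix_degenerate_error")
  }
  frames <- as_cube(traj$coords[, idx, , drop = FALSE])
  out <- rigid_series_cpp(frames, ref[idx, , drop = FALSE])
  out$reference <- ref
  structure(out, class = "rigid_pose_series")
}

#' Per-frame head-motion magnitude
#'
#' Quantifies rigid head motion as the frame-to-frame displacement of the
#' head-region centroid under the estimated rigid pose, plus a rotation
#' term: the mean arc length travelled by the head-region landmarks under
#' the incremental rotation between consecutive frames. The magnitude of
#' frame 0 is 0.
#'
#' @inheritParams rigid_pose_series
#' @return Numeric vector of length T (frames).
#' @export
head_motion_series <- function(traj, reference_frame_policy = "neutral") {
  pose <- rigid_pose_series(traj, reference_frame_policy)
  head_series_from_pose(pose, traj)
}

head_series_from_pose <- function(pose, traj) {
  idx <- traj$mesh$region_map$head_rigid
  ref_pts <- pose$reference[idx, , drop = FALSE]
  cen <- colMeans(ref_pts)
  rel <- sweep(ref_pts, 2, cen)
  as.numeric(head_series_cpp(pose$rotation, pose$translation, rel, cen))
}

#' Per-frame motion magnitude of a facial region
#'
#' Mean per-landmark frame-to-frame Euclidean displacement within a named
#' region. With `remove_rigid = TRUE` (default) every frame is first
#' re-expressed in the head-stabilized coordinate frame, so the series
#' reflects facial-muscle deformation only and vanishes under purely
#' rigid motion. The magnitude of frame 0 is 0.
#'
#' @inheritParams rigid_pose_series
#' @param region Region name from the mesh's region map.
#' @param remove_rigid Stabilize head motion first?
#' @return Numeric vector of length T.
#' @export
region_motion_series <- function(traj, region, remove_rigid = TRUE,
                                 reference_frame_policy = "neutral") {
  rm <- traj$mesh$region_map
  if (!region %in% names(rm)) {
    stopf("unknown region '%s' (available: %s)", region,
          paste(names(rm), collapse = ", "))
  }
  coords <- traj$coords
  if (isTRUE(remove_rigid)) {
    pose <- rigid_pose_series(traj, reference_frame_policy)
    coords <- from_cube(stabilize_cpp(as_cube(coords), pose$rotation,
                                      pose$translation))
  }
  steps <- step_lengths(coords[, rm[[region]], , drop = FALSE])
  c(0, rowMeans(steps))
}

#' Total moving distance of a magnitude series
#'
#' Path length: the sum of per-frame motion magnitudes over the trial.
#'
#' @param series Numeric per-frame magnitude series.
#' @return A single number.
#' @export
moving_distance <- function(series) {
  if (any(!is.finite(series))) stopf("magnitude series must be finite")
  sum(series)
}

#' Decompose a trajectory into named motion channels
#'
#' Computes the per-frame magnitude series used throughout the analysis:
#' `overall` (mean per-landmark displacement over all landmarks, rigid
#' motion *not* removed), `head` (rigid head motion via
#' [head_motion_series()]), and `left_periocular`, `right_periocular`,
#' `perioral` (head-stabilized region series).
#'
#' @inheritParams rigid_pose_series
#' @param remove_rigid Stabilize head motion for the facial-muscle
#'   channels (default `TRUE`; set `FALSE` to measure them in world
#'   coordinates).
#' @return An object of class `motion_channels`: a list with `channels`
#'   (named list of length-T numeric series), `fps`, `duration_s`, `meta`.
#' @export
compute_channels <- function(traj, remove_rigid = TRUE,
                             reference_frame_policy = "neutral") {
  stopifnot(inherits(traj, "landmark_trajectory"))
  coords <- traj$coords
  rm <- traj$mesh$region_map
  overall <- as.numeric(mean_step_cpp(as_cube(coords)))
  pose <- rigid_pose_series(traj, reference_frame_policy)
  head_s <- head_series_from_pose(pose, traj)
  sub_idx <- c(rm$left_periocular, rm$right_periocular, rm$perioral)
  sub <- as_cube(coords[, sub_idx, , drop = FALSE])
  if (isTRUE(remove_rigid)) {
    sub <- stabilize_cpp(sub, pose$rotation, pose$translation)
  }
  region_series <- function(region) {
    loc <- match(rm[[region]], sub_idx)
    as.numeric(mean_step_cpp(sub[loc, , , drop = FALSE]))
  }
  structure(
    list(
      channels = list(
        overall = overall,
        head = head_s,
        left_periocular = region_series("left_periocular"),
        right_periocular = region_series("right_periocular"),
        perioral = region_series("perioral")
      ),
      fps = traj$fps,
      duration_s = dim(coords)[1] / traj$fps,
      meta = traj$meta
    ),
    class = "motion_channels"
  )
}

#' @export
print.motion_channels <- function(x, ...) {
  cat(sprintf("<motion_channels> %d frames @ %g fps; channels: %s\n",
              length(x$channels[[1]]), x$fps,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Convert motion channels to a long tibble
#'
#' @param x A [motion_channels][compute_channels] object.
#' @param ... Unused.
#' @return A tibble with columns `frame`, `time_s`, `channel`, `magnitude`.
#' @export
as_tibble.motion_channels <- function(x, ...) {
  T <- length(x$channels[[1]])
  purrr::imap_dfr(x$channels, function(series, name) {
    tibble::tibble(frame = seq_len(T) - 1L, time_s = (seq_len(T) - 1L) / x$fps,
                   channel = name, magnitude = series)
  })
}

#' Per-trial moving-distance summary of a trajectory
#'
#' Convenience wrapper: computes the channel set and returns the moving
#' distances the study reports (whole face, head, left/right eye, lip) as
#' a one-row tibble.
#'
#' @inheritParams compute_channels
#' @return A one-row tibble with columns `dist_overall`, `dist_head`,
#'   `dist_eye_l`, `dist_eye_r`, `dist_lip`.
#' @export
moving_distances <- function(traj, remove_rigid = TRUE) {
  ch <- compute_channels(traj, remove_rigid = remove_rigid)
  tibble::tibble(
    dist_overall = moving_distance(ch$channels$overall),
    dist_head = moving_distance(ch$channels$head),
    dist_eye_l = moving_distance(ch$channels$left_periocular),
    dist_eye_r = moving_distance(ch$channels$right_periocular),
    dist_lip = moving_distance(ch$channels$perioral)
  )
}
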