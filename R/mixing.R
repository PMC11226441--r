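#' Mixing configuration for the control manipulation
#'
#' The paradigm manipulates control by driving the displayed face with a
#' convex combination of two actors' motion: the participant's
#' displacement field gets weight `w` and the second actor's `1 - w`
#' (`w = 1` full control, `w = 0.5` partial control), and the display lags
#' the movement by a fixed latency (default 9 frames, i.e. ~300 ms at
#' 30 fps).
#'
#' @param w Participant weight in `[0, 1]`.
#' @param latency_frames Non-negative integer display latency in frames.
#' @param renormalize If `TRUE`, each mixed frame is rescaled so its mean
#'   displacement norm equals the convex combination of the input norms
#'   (off by default: a plain convex combination halves the amplitude when
#'   only one actor moves, but leaves that actor full *directional*
#'   control).
#' @return An object of class `mixing_config`.
#' @export
mixing_config <- function(w = 0.5, latency_frames = 9L, renormalize = FALSE) {
  check_number(w, "w", 0, 1)
  latency_frames <- check_count(latency_frames, "latency_frames", lower = 0L)
  structure(list(w = w, latency_frames = latency_frames,
                 renormalize = isTRUE(renormalize)),
            class = "mixing_config")
}

#' Mix two displacement fields at a control ratio
#'
#' Frame-wise convex combination `w * disp_a + (1 - w) * disp_b` of two
#' actors' displacement-from-neutral fields on the same topology.
#'
#' @param disp_a,disp_b T x K x 3 displacement arrays of equal dimension.
#' @param w Weight of `disp_a` in `[0, 1]`.
#' @param renormalize See [mixing_config()].
#' @return A T x K x 3 mixed displacement array.
#' @export
mix_displacements <- function(disp_a, disp_b, w, renormalize = FALSE) {
  check_number(w, "w", 0, 1)
  if (!identical(dim(disp_a), dim(disp_b))) {
    stopf("displacement fields disagree in shape: %s vs %s",
          paste(dim(disp_a), collapse = "x"), paste(dim(disp_b), collapse = "x"))
  }
  mixed <- w * disp_a + (1 - w) * disp_b
  if (isTRUE(renormalize)) {
    target <- w * frame_norms(disp_a) + (1 - w) * frame_norms(disp_b)
    actual <- frame_norms(mixed)
    scale <- ifelse(actual > 1e-12, target / actual, 1)
    mixed <- mixed * array(scale, dim = dim(mixed))
  }
  mixed
}

# Per-frame mean displacement norm of a T x K x 3 field.
frame_norms <- function(disp) {
  rowMeans(matrix(sqrt(disp[, , 1]^2 + disp[, , 2]^2 + disp[, , 3]^2),
                  nrow = dim(disp)[1]))
}

#' Delay a trajectory or displacement field by a fixed latency
#'
#' Frame `t` of the output equals frame `max(0, t - latency_frames)` of
#' the input (0-based): the series is shifted and front-padded with its
#' first frame, emulating a constant display latency.
#'
#' @param x A [landmark_trajectory()] or a T x K x 3 array.
#' @param latency_frames Non-negative integer delay, strictly less than
#'   the number of frames.
#' @return Same type as `x`.
#' @export
apply_latency <- function(x, latency_frames) {
  latency_frames <- check_count(latency_frames, "latency_frames", lower = 0L)
  if (inherits(x, "landmark_trajectory")) {
    out <- x
    out$coords <- delay_array(x$coords, latency_frames)
    return(out)
  }
  delay_array(x, latency_frames)
}

delay_array <- function(coords, lag) {
  T <- dim(coords)[1]
  if (lag >= T) stopf("latency (%d frames) must be shorter than the trajectory (%d frames)", lag, T)
  if (lag == 0L) return(coords)
  idx <- pmax(seq_len(T) - lag, 1L)
  coords[idx, , , drop = FALSE]
}

#' Render the displayed face from mixed displacements
#'
#' The displayed stimulus is a target identity's neutral mesh animated by
#' the (latency-delayed) mixed displacement field. The target mesh may
#' belong to a different identity than the motion source — identity is
#' carried by the static face, motion by the displacement field — as long
#' as both share a topology.
#'
#' @param target_mesh The [neutral_mesh][make_neutral_mesh] of the face
#'   shown on screen.
#' @param mixed_displacements T x K x 3 displacement array.
#' @param config A [mixing_config()] (only its latency is used here).
#' @param fps Frame rate of the rendered trajectory.
#' @param meta Optional meta list.
#' @return A [landmark_trajectory()] on `target_mesh`.
#' @export
render_displayed <- function(target_mesh, mixed_displacements,
                             config = mixing_config(), fps = 30, meta = list()) {
  validate_mesh(target_mesh)
  if (dim(mixed_displacements)[2] != target_mesh$K) {
    stopf("displacement field has %d landmarks but target mesh has %d",
          dim(mixed_displacements)[2], target_mesh$K)
  }
  delayed <- delay_array(mixed_displacements, config$latency_frames)
  coords <- sweep_frames(delayed, target_mesh$coords, `+`)
  landmark_trajectory(coords, fps = fps, mesh = target_mesh, meta = meta)
}
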