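#' Landmark trajectory objects
#'
#' A landmark trajectory is the unit of all motion analysis: a T x K x 3
#' array of dimensionless 3D landmark coordinates sampled at `fps`
#' frames/s, tied to the [neutral mesh][make_neutral_mesh] it animates
#' (which also carries the region map). Frame indices are 0-based in the
#' file format; time of frame `f` is `f / fps` seconds.
#'
#' @param coords T x K x 3 numeric array of landmark coordinates.
#' @param fps Frame rate in frames/s.
#' @param mesh The [neutral_mesh][make_neutral_mesh] the trajectory animates.
#' @param meta Optional named list of trial identifiers.
#' @return An object of class `landmark_trajectory`.
#' @export
landmark_trajectory <- function(coords, fps, mesh, meta = list()) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stopf("`coords` must be a T x K x 3 array")
  }
  if (dim(coords)[1] < 2L) stopf("a trajectory needs at least 2 frames")
  if (!all(is.finite(coords))) stopf("trajectory coordinates must be finite")
  check_number(fps, "fps", lower = 1e-9)
  validate_mesh(mesh)
  if (dim(coords)[2] != mesh$K) {
    stopf("trajectory has %d landmarks but mesh '%s' has %d",
          dim(coords)[2], mesh$topology_id, mesh$K)
  }
  structure(
    list(coords = coords, fps = fps, mesh = mesh, meta = meta),
    class = "landmark_trajectory"
  )
}

n_frames <- function(traj) dim(traj$coords)[1]

#' Displacement-from-neutral field of a trajectory
#'
#' Subtracts the trajectory's neutral mesh from every frame. Displacement
#' fields are the representation on which motion mixing and control-error
#' computation operate: they are identity-free, so motion recorded on one
#' face can animate another face with the same topology.
#'
#' @param traj A [landmark_trajectory()].
#' @return A T x K x 3 displacement array.
#' @export
displacement_field <- function(traj) {
  stopifnot(inherits(traj, "landmark_trajectory"))
  sweep_frames(traj$coords, traj$mesh$coords, `-`)
}

# Apply `op` between every frame (K x 3) and a fixed K x 3 matrix. The
# (T, K, 3) layout is column-major with time fastest, so the matrix
# broadcasts with a single `each = T` replication.
sweep_frames <- function(coords, mat, op) {
  op(coords, rep(as.numeric(mat), each = dim(coords)[1]))
}

#' @export
print.landmark_trajectory <- function(x, ...) {
  dm <- dim(x$coords)
  cat(sprintf(
    "<landmark_trajectory> %d frames x %d landmarks @ %g fps (%.1f s, topology '%s')\n",
    dm[1], dm[2], x$fps, dm[1] / x$fps, x$mesh$topology_id))
  invisible(x)
}

#' Convert a trajectory to a long tibble
#'
#' @param x A [landmark_trajectory()].
#' @param ... Unused.
#' @return A tibble with columns `frame` (0-based), `time_s`,
#'   `landmark_id` (0-based), `x`, `y`, `z`.
#' @export
as_tibble.landmark_trajectory <- function(x, ...) {
  dm <- dim(x$coords)
  fps <- x$fps
  cx <- as.vector(x$coords[, , 1])
  cy <- as.vector(x$coords[, , 2])
  cz <- as.vector(x$coords[, , 3])
  tibble::tibble(
    frame = rep(seq_len(dm[1]) - 1L, times = dm[2]),
    landmark_id = rep(seq_len(dm[2]) - 1L, each = dm[1]),
    x = cx, y = cy, z = cz
  ) |>
    dplyr::mutate(time_s = .data$frame / fps, .after = "frame") |>
    dplyr::arrange(.data$frame, .data$landmark_id)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Write / read a trajectory as long CSV
#'
#' The on-disk format is one row per frame x landmark with columns
#' `trial_id, frame, landmark_id, x, y, z` (0-based frame and landmark
#' indices). The frame rate and mesh are not stored in the CSV and must be
#' supplied again on read.
#'
#' @param traj A [landmark_trajectory()].
#' @param path File path.
#' @param trial_id Identifier written to the `trial_id` column.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns a [landmark_trajectory()].
#' @export
write_trajectory_csv <- function(traj, path, trial_id = traj$meta$trial_id %||% "trial") {
  df <- as_tibble(traj) |>
    dplyr::transmute(trial_id = trial_id, .data$frame, .data$landmark_id,
                     .data$x, .data$y, .data$z)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param fps,mesh Frame rate and mesh to attach on read.
#' @export
read_trajectory_csv <- function(path, fps, mesh) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("frame", "landmark_id", "x", "y", "z")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stopf("trajectory file '%s' lacks columns: %s", path,
          paste(missing_cols, collapse = ", "))
  }
  df <- dplyr::arrange(df, .data$frame, .data$landmark_id)
  T <- length(unique(df$frame))
  K <- length(unique(df$landmark_id))
  if (nrow(df) != T * K) stopf("trajectory file '%s' is not a full frame x landmark grid", path)
  coords <- array(0, dim = c(T, K, 3))
  coords[, , 1] <- matrix(df$x, nrow = T, byrow = TRUE)
  coords[, , 2] <- matrix(df$y, nrow = T, byrow = TRUE)
  coords[, , 3] <- matrix(df$z, nrow = T, byrow = TRUE)
  meta <- list(trial_id = if ("trial_id" %in% names(df)) df$trial_id[1] else NULL)
  landmark_trajectory(coords, fps = fps, mesh = mesh, meta = meta)
}
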