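# Shared fixtures and independent oracles for the test suite.

toy_mesh <- function(K = 64L) make_neutral_mesh("toy", K)

# A trajectory that just repeats the neutral mesh for T frames.
static_trajectory <- function(mesh, T = 60L, fps = 30) {
  coords <- aperm(array(t(mesh$coords), dim = c(3, mesh$K, T)), c(3, 2, 1))
  landmark_trajectory(coords, fps = fps, mesh = mesh)
}

# Apply a fixed rotation (about the centroid of `about_idx`) plus a
# translation to every frame of a trajectory.
transform_trajectory <- function(traj, R = diag(3), trans = c(0, 0, 0),
                                 about = c(0, 0, 0)) {
  out <- traj
  T <- dim(traj$coords)[1]
  for (t in seq_len(T)) {
    fr <- traj$coords[t, , ]
    out$coords[t, , ] <- sweep(sweep(fr, 2, about) %*% t(R), 2,
                               about + trans, `+`)
  }
  out
}

rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

rot_axis <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}

# Brute-force rigid alignment oracle: direct minimization over Euler
# angles and translation (independent of the SVD route).
brute_rigid_align <- function(frame, ref) {
  obj <- function(par) {
    R <- rot_euler(par[1:3])
    fit <- ref %*% t(R) + matrix(par[4:6], nrow(ref), 3, byrow = TRUE)
    sum((frame - fit)^2)
  }
  best <- NULL
  for (init in list(rep(0, 6), c(0.3, -0.2, 0.1, 0, 0, 0),
                    c(-0.4, 0.5, -0.3, 0.1, -0.1, 0))) {
    o <- stats::optim(init, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(rotation = rot_euler(best$par[1:3]), translation = best$par[4:6],
       residual = sqrt(best$value / nrow(ref)))
}

rot_euler <- function(a) {
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Brute-force sums-of-squares decomposition of the 2x2 within design.
# cell_means: data frame with participant, face, control, mean_value.
brute_rm_anova <- function(cell_means) {
  y <- cell_means$mean_value
  p <- factor(cell_means$participant)
  a <- factor(cell_means$face)
  b <- factor(cell_means$control)
  n <- nlevels(p)
  g <- mean(y)
  m_a <- tapply(y, a, mean); m_b <- tapply(y, b, mean)
  m_p <- tapply(y, p, mean)
  m_ab <- tapply(y, list(a, b), mean)
  m_ap <- tapply(y, list(a, p), mean)
  m_bp <- tapply(y, list(b, p), mean)
  ss_a <- 2 * n * sum((m_a - g)^2)
  ss_b <- 2 * n * sum((m_b - g)^2)
  ss_ab <- n * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + g)^2)
  ss_as <- 2 * sum((m_ap - outer(m_a, rep(1, n)) -
                      outer(rep(1, 2), m_p) + g)^2)
  ss_bs <- 2 * sum((m_bp - outer(m_b, rep(1, n)) -
                      outer(rep(1, 2), m_p) + g)^2)
  resid <- y
  for (i in seq_along(y)) {
    ai <- as.integer(a[i]); bi <- as.integer(b[i]); pi <- as.integer(p[i])
    resid[i] <- y[i] - m_ab[ai, bi] - m_ap[ai, pi] - m_bp[bi, pi] +
      m_a[ai] + m_b[bi] + m_p[pi] - g
  }
  ss_abs <- sum(resid^2)
  list(
    face = (ss_a / 1) / (ss_as / (n - 1)),
    control = (ss_b / 1) / (ss_bs / (n - 1)),
    interaction = (ss_ab / 1) / (ss_abs / (n - 1))
  )
}

# Random complete 2x2 within-design cell-mean table.
random_cell_means <- function(n = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tidyr::expand_grid(
    participant = sprintf("P%02d", seq_len(n)),
    face = c("self", "other"), control = c("full", "partial")
  ) |>
    dplyr::mutate(mean_value = rnorm(dplyr::n(), mean = 50, sd = 10))
}
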