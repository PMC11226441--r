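// Per-frame rigid (Kabsch) alignment and pose application.
// Trajectories cross the C++ boundary as cubes of dimension (K, 3, T):
// slice t is the K x 3 coordinate matrix of frame t.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Compose intrinsic rotations Rz(roll) * Ry(yaw) * Rx(pitch), one per frame.
// angles: T x 3 (pitch, yaw, roll) in radians.
// [[Rcpp::export]]
arma::cube euler_rotations_cpp(const arma::mat& angles) {
  const uword T = angles.n_rows;
  cube R(3, 3, T);
  for (uword t = 0; t < T; ++t) {
    const double cx = std::cos(angles(t, 0)), sx = std::sin(angles(t, 0));
    const double cy = std::cos(angles(t, 1)), sy = std::sin(angles(t, 1));
    const double cz = std::cos(angles(t, 2)), sz = std::sin(angles(t, 2));
    mat Rx = {{1, 0, 0}, {0, cx, -sx}, {0, sx, cx}};
    mat Ry = {{cy, 0, sy}, {0, 1, 0}, {-sy, 0, cy}};
    mat Rz = {{cz, -sz, 0}, {sz, cz, 0}, {0, 0, 1}};
    R.slice(t) = Rz * Ry * Rx;
  }
  return R;
}

// Apply frame-wise rigid pose to a base point set: out_t = base * R_t' + 1 t_t'.
// [[Rcpp::export]]
arma::cube apply_pose_cpp(const arma::mat& base, const arma::cube& R,
                          const arma::mat& trans) {
  const uword T = R.n_slices, K = base.n_rows;
  cube out(K, 3, T);
  for (uword t = 0; t < T; ++t) {
    out.slice(t) = base * R.slice(t).t();
    out.slice(t).each_row() += trans.row(t);
  }
  return out;
}

// Least-squares rigid transform (no scaling) of `ref` onto each frame,
// solved by SVD of the cross-covariance with a reflection guard.
// Returns rotations (3x3xT), translations (Tx3) and per-frame RMS residuals.
// [[Rcpp::export]]
Rcpp::List rigid_series_cpp(const arma::cube& frames, const arma::mat& ref) {
  const uword T = frames.n_slices, K = ref.n_rows;
  cube Rout(3, 3, T);
  mat tout(T, 3);
  vec resid(T);
  const rowvec cref = mean(ref, 0);
  const mat refc = ref.each_row() - cref;
  mat U, V;
  vec s;
  for (uword t = 0; t < T; ++t) {
    const mat& F = frames.slice(t);
    rowvec cf = mean(F, 0);
    mat Fc = F.each_row() - cf;
    mat H = refc.t() * Fc;
    svd(U, s, V, H);
    mat R = V * U.t();
    if (det(R) < 0) {  // reflection guard: flip the weakest axis
      V.col(2) *= -1.0;
      R = V * U.t();
    }
    Rout.slice(t) = R;
    rowvec tr = cf - cref * R.t();
    tout.row(t) = tr;
    mat fit = ref * R.t();
    fit.each_row() += tr;
    resid(t) = std::sqrt(accu(square(F - fit)) / (double)K);
  }
  return Rcpp::List::create(Rcpp::Named("rotation") = Rout,
                            Rcpp::Named("translation") = tout,
                            Rcpp::Named("residual") = resid);
}

// Topographic prominence of candidate local maxima (1-based indices):
// height above the higher of the two flanking saddles, where each saddle
// is the minimum between the peak and the nearest higher point (or the
// series end).
// [[Rcpp::export]]
arma::vec prominences_cpp(const arma::vec& series, const arma::ivec& cand) {
  const int n = series.n_elem;
  vec out(cand.n_elem);
  for (uword j = 0; j < cand.n_elem; ++j) {
    const int i = cand(j) - 1;
    const double h = series(i);
    double m = datum::inf, base_l, base_r;
    int k = i - 1;
    for (; k >= 0 && series(k) <= h; --k) m = std::min(m, series(k));
    base_l = (k >= 0) ? m : series.subvec(0, i - 1).min();
    m = datum::inf;
    k = i + 1;
    for (; k < n && series(k) <= h; ++k) m = std::min(m, series(k));
    base_r = (k < n) ? m : series.subvec(i + 1, n - 1).min();
    out(j) = h - std::max(base_l, base_r);
  }
  return out;
}

// Mean per-landmark frame-to-frame displacement of a (K,3,T) cube;
// element 0 of the result is 0.
// [[Rcpp::export]]
arma::vec mean_step_cpp(const arma::cube& coords) {
  const uword T = coords.n_slices, K = coords.n_rows;
  vec out(T, fill::zeros);
  for (uword t = 1; t < T; ++t) {
    const mat d = coords.slice(t) - coords.slice(t - 1);
    out(t) = accu(sqrt(sum(square(d), 1))) / (double)K;
  }
  return out;
}

// Head-motion magnitude series from an estimated rigid pose series:
// frame-to-frame displacement of the transformed region centroid plus the
// mean arc length of the region points under the incremental rotation.
// `rel` holds the reference head points relative to their centroid `cen`.
// [[Rcpp::export]]
arma::vec head_series_cpp(const arma::cube& R, const arma::mat& trans,
                          const arma::mat& rel, const arma::vec& cen) {
  const uword T = R.n_slices;
  vec out(T, fill::zeros);
  vec prev_c = R.slice(0) * cen + trans.row(0).t();
  for (uword t = 1; t < T; ++t) {
    vec cur_c = R.slice(t) * cen + trans.row(t).t();
    double d_cent = norm(cur_c - prev_c);
    mat dR = R.slice(t) * R.slice(t - 1).t();
    double c = std::clamp((trace(dR) - 1.0) / 2.0, -1.0, 1.0);
    double ang = std::acos(c);
    double rot_term = 0.0;
    vec axis = {dR(2, 1) - dR(1, 2), dR(0, 2) - dR(2, 0), dR(1, 0) - dR(0, 1)};
    // acos near 1 amplifies rounding; a zero axis means no real rotation
    if (ang > 1e-7 && norm(axis) > 1e-12) {
      axis /= norm(axis);
      mat rel_t = rel * R.slice(t - 1).t();
      vec along = rel_t * axis;
      vec d_axis = sqrt(clamp(sum(square(rel_t), 1) - square(along),
                              0.0, datum::inf));
      rot_term = ang * mean(d_axis);
    }
    out(t) = d_cent + rot_term;
    prev_c = cur_c;
  }
  return out;
}

// Rotate a frame-wise vector field: out_t = D_t * R_t'. Used to express
// facial deformations (defined in the head-local frame) in world space.
// [[Rcpp::export]]
arma::cube rotate_fields_cpp(const arma::cube& D, const arma::cube& R) {
  const uword T = D.n_slices;
  cube out(D.n_rows, 3, T);
  for (uword t = 0; t < T; ++t) out.slice(t) = D.slice(t) * R.slice(t).t();
  return out;
}

// Undo frame-wise rigid pose: out_t = (coords_t - 1 t_t') * R_t
// (i.e. re-express every frame in the reference head coordinate frame).
// [[Rcpp::export]]
arma::cube stabilize_cpp(const arma::cube& coords, const arma::cube& R,
                         const arma::mat& trans) {
  const uword T = coords.n_slices;
  cube out(coords.n_rows, 3, T);
  for (uword t = 0; t < T; ++t) {
    mat shifted = coords.slice(t);
    shifted.each_row() -= trans.row(t);
    out.slice(t) = shifted * R.slice(t);
  }
  return out;
}
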