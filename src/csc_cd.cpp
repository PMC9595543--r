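#include <Rcpp.h>
using namespace Rcpp;

// Coordinate descent for the per-epoch non-negative convolutional lasso:
//   min_z 0.5 * z' G z - b' z + lambda * sum(z),  z >= 0
// where z stacks K activation rows of length P and the Gram factorizes as
//   G[(k,t),(k2,t2)] = udot(k,k2) * vcc(k,k2, t - t2),   |t - t2| < L.
//
// b:    K x P correlations of the epoch with every shifted atom
// udot: K x K spatial inner products u_k . u_k2
// vcc:  K x K x (2L-1) temporal cross-correlations,
//       vcc(k,k2,d) = sum_l v_k[l] * v_k2[l + d],  d = -(L-1)..(L-1)
// z:    K x P, updated in place (warm start)
// A running vector q = G z is maintained; each coordinate update costs
// O(K L) only when the coordinate actually moves.
// [[Rcpp::export]]
List csc_cd_epoch(NumericMatrix b, NumericMatrix udot, NumericVector vcc,
                  int L, NumericMatrix z, double lambda,
                  int max_sweeps = 100, double tol = 1e-7) {
  const int K = b.nrow(), P = b.ncol();
  std::vector<double> q(K * P, 0.0);   // q[k + K*t] = (G z)[k,t]

  // initialize q from the warm start
  for (int k2 = 0; k2 < K; ++k2)
    for (int t2 = 0; t2 < P; ++t2) {
      double zv = z(k2, t2);
      if (zv == 0.0) continue;
      int tlo = std::max(0, t2 - L + 1), thi = std::min(P - 1, t2 + L - 1);
      for (int k = 0; k < K; ++k) {
        double ud = udot(k, k2);
        if (ud == 0.0) continue;
        for (int t = tlo; t <= thi; ++t) {
          // vcc index: (k, k2, d) with d = t - t2 in [-(L-1), L-1]
          double g = ud * vcc[k + K * (k2 + K * (t - t2 + L - 1))];
          q[k + K * t] += g * zv;
        }
      }
    }

  double maxdiag = 0.0;
  std::vector<double> diag(K);
  for (int k = 0; k < K; ++k) {
    diag[k] = udot(k, k) * vcc[k + K * (k + K * (L - 1))];
    if (diag[k] > maxdiag) maxdiag = diag[k];
  }

  // convergence threshold on the largest coordinate move, relative to the
  // typical activation magnitude implied by the correlations
  double bmax = 0.0;
  for (int k = 0; k < K; ++k)
    for (int t = 0; t < P; ++t)
      if (std::abs(b(k, t)) > bmax) bmax = std::abs(b(k, t));
  double zscale = (maxdiag > 0.0) ? bmax / maxdiag : 1.0;
  double move_tol = tol * std::max(zscale, 1e-12);

  int sweeps = 0;
  for (int s = 0; s < max_sweeps; ++s) {
    double maxmove = 0.0;
    for (int k = 0; k < K; ++k) {
      if (diag[k] <= 0.0) continue;
      for (int t = 0; t < P; ++t) {
        double zold = z(k, t);
        double grad_rest = q[k + K * t] - diag[k] * zold;
        double znew = (b(k, t) - lambda - grad_rest) / diag[k];
        if (znew < 0.0) znew = 0.0;
        double delta = znew - zold;
        if (delta == 0.0) continue;
        z(k, t) = znew;
        if (std::abs(delta) > maxmove) maxmove = std::abs(delta);
        int tlo = std::max(0, t - L + 1), thi = std::min(P - 1, t + L - 1);
        for (int k2 = 0; k2 < K; ++k2) {
          double ud = udot(k2, k);
          if (ud == 0.0) continue;
          for (int t2 = tlo; t2 <= thi; ++t2) {
            double g = ud * vcc[k2 + K * (k + K * (t2 - t + L - 1))];
            q[k2 + K * t2] += g * delta;
          }
        }
      }
    }
    sweeps = s + 1;
    if (maxmove <= move_tol) break;
  }
  return List::create(Named("z") = z, Named("sweeps") = sweeps);
}
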