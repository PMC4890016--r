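#include <Rcpp.h>
using namespace Rcpp;

// Joint bilinear-neural + balloon-windkessel integration.
//
// Neural states z (one per region) follow
//   dz/dt = (A + sum_j u_j B[j]) z + C u
// and each region carries four haemodynamic states (s, f, v, q):
//   ds/dt = z - kappa s - gamma (f - 1)
//   df/dt = s
//   dv/dt = (f - v^(1/alpha)) / tau
//   dq/dt = (f E(f,E0)/E0 - v^(1/alpha) q / v) / tau,  E(f,E0) = 1-(1-E0)^(1/f)
// BOLD readout: y = 100 V0 [k1 (1-q) + k2 (1-q/v) + k3 (1-v)],
//   k1 = 7 E0, k2 = 2, k3 = 2 E0 - 0.2  (percent signal change).
//
// Inputs u are piecewise-constant over microtime bins; integration is
// fixed-step RK4 with one step per bin. Scans are read out at the state
// reached at the start of the bins listed in scan_idx (0-based).

struct DcmSys {
  int n;                      // regions
  int m;                      // inputs
  const double *A;            // n x n, column-major
  const double *B;            // n x n x m
  const double *C;            // n x m
  const double *hemo;         // n x 6: kappa, gamma, tau, alpha, E0, V0
};

static inline void deriv(const DcmSys &S, const double *x, const double *u,
                         double *dx) {
  const int n = S.n;
  // effective connectivity J = A + sum_j u_j B_j applied to z, plus C u
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int k = 0; k < n; ++k) {
      double a = S.A[i + n * k];
      for (int j = 0; j < S.m; ++j)
        if (u[j] != 0.0) a += u[j] * S.B[i + n * k + n * n * j];
      acc += a * x[k];
    }
    for (int j = 0; j < S.m; ++j) acc += S.C[i + n * j] * u[j];
    dx[i] = acc;
  }
  for (int i = 0; i < n; ++i) {
    // hemo is column-major n x 6: kappa, gamma, tau, alpha, E0, V0
    double kappa = S.hemo[i], gamma = S.hemo[i + n], tau = S.hemo[i + 2 * n],
           alpha = S.hemo[i + 3 * n], E0 = S.hemo[i + 4 * n];
    double z = x[i];
    double s = x[n + 4 * i + 0];
    double f = x[n + 4 * i + 1];
    double v = x[n + 4 * i + 2];
    double q = x[n + 4 * i + 3];
    if (f < 1e-6) f = 1e-6;
    if (v < 1e-6) v = 1e-6;
    if (q < 1e-9) q = 1e-9;
    double fv = std::pow(v, 1.0 / alpha);
    double E = 1.0 - std::pow(1.0 - E0, 1.0 / f);
    dx[n + 4 * i + 0] = z - kappa * s - gamma * (f - 1.0);
    dx[n + 4 * i + 1] = s;
    dx[n + 4 * i + 2] = (f - fv) / tau;
    dx[n + 4 * i + 3] = (f * E / E0 - fv * q / v) / tau;
  }
}

// [[Rcpp::export(name = ".dcm_integrate_cpp")]]
NumericMatrix dcm_integrate_cpp(NumericMatrix A, NumericVector Barr,
                                NumericMatrix C, NumericMatrix U,
                                NumericMatrix hemo, double dt,
                                IntegerVector scan_idx) {
  const int n = A.nrow();
  const int m = C.ncol();
  const int n_bins = U.nrow();
  if (U.ncol() != m) stop("input matrix has %d columns, expected %d", U.ncol(), m);
  if (hemo.nrow() != n || hemo.ncol() != 6) stop("hemo must be n_regions x 6");
  if (Barr.size() != n * n * m) stop("B array has wrong length");

  DcmSys S;
  S.n = n; S.m = m;
  S.A = A.begin(); S.B = Barr.begin(); S.C = C.begin(); S.hemo = hemo.begin();

  const int ns = 5 * n;
  std::vector<double> x(ns, 0.0), k1(ns), k2(ns), k3(ns), k4(ns), tmp(ns);
  // rest state: z = s = 0, f = v = q = 1
  for (int i = 0; i < n; ++i) {
    x[n + 4 * i + 1] = 1.0;
    x[n + 4 * i + 2] = 1.0;
    x[n + 4 * i + 3] = 1.0;
  }

  const int n_scans = scan_idx.size();
  NumericMatrix Y(n_scans, n);
  int next_scan = 0;

  for (int b = 0; b <= n_bins; ++b) {
    while (next_scan < n_scans && scan_idx[next_scan] == b) {
      for (int i = 0; i < n; ++i) {
        double E0 = hemo(i, 4), V0 = hemo(i, 5);
        double v = x[n + 4 * i + 2], q = x[n + 4 * i + 3];
        double k1c = 7.0 * E0, k2c = 2.0, k3c = 2.0 * E0 - 0.2;
        Y(next_scan, i) =
            100.0 * V0 * (k1c * (1.0 - q) + k2c * (1.0 - q / v) + k3c * (1.0 - v));
      }
      ++next_scan;
    }
    if (b == n_bins) break;
    const double *u = U.begin();
    std::vector<double> ub(m);
    for (int j = 0; j < m; ++j) ub[j] = u[b + n_bins * j];
    deriv(S, x.data(), ub.data(), k1.data());
    for (int i = 0; i < ns; ++i) tmp[i] = x[i] + 0.5 * dt * k1[i];
    deriv(S, tmp.data(), ub.data(), k2.data());
    for (int i = 0; i < ns; ++i) tmp[i] = x[i] + 0.5 * dt * k2[i];
    deriv(S, tmp.data(), ub.data(), k3.data());
    for (int i = 0; i < ns; ++i) tmp[i] = x[i] + dt * k3[i];
    deriv(S, tmp.data(), ub.data(), k4.data());
    for (int i = 0; i < ns; ++i)
      x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    for (int i = 0; i < ns; ++i)
      if (!std::isfinite(x[i]))
        stop("integration diverged at t = %.3f s (bin %d)", (b + 1) * dt, b + 1);
  }
  if (next_scan < n_scans) stop("scan index beyond the integrated interval");
  return Y;
}
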